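# Stiffness/spectral analysis and independent reference solvers.

# Dense internal matrix M_i of one SCC block: the linear self-coupling
# (within-block production plus the eliminating/consumption diagonal),
# with the pool-size inverse folded in.
block_internal_matrix <- function(sys, b) {
  bl <- sys$blocks[[b]]
  M <- matrix(0, bl$nb, bl$nb)
  li <- bl$meta$lin
  for (k in seq_along(li$t)) {
    s <- li$s[k]
    if (!is.na(s) && s <= sys$nx && sys$node_tab$block[s] == b) {
      M[bl$loc[li$t[k]], bl$loc[s]] <- M[bl$loc[li$t[k]], bl$loc[s]] +
        li$unit[k] * sys$fluxvec_all[li$rxn[k]]
    }
  }
  M
}

#' Stiffness ratio of a square matrix
#'
#' Ratio between the largest and the smallest magnitude of the real
#' parts of the eigenvalues.  When the smallest real part magnitude is
#' (numerically) zero the ratio is undefined and `NA` is returned with
#' attribute `undefined = TRUE`.
#'
#' @param M square numeric matrix.
#' @param zero_tol threshold below which a real part counts as zero.
#' @export
stiffness_ratio <- function(M, zero_tol = 1e-12) {
  stopifnot(is.matrix(M), nrow(M) == ncol(M))
  re <- abs(Re(eigen(M, only.values = TRUE)$values))
  if (min(re) <= zero_tol) {
    return(structure(NA_real_, undefined = TRUE))
  }
  max(re) / min(re)
}

#' Spectral stability report of a cascade system
#'
#' Eigenvalues of every SCC block's internal matrix; for flux-balanced
#' models all real parts are expected to be strictly negative (a stable
#' isotope ODE cascade).  Imaginary parts are reported, not assumed
#' zero.
#'
#' @param sys a `cascade_system`.
#' @param zero_tol threshold for flagging a non-negative real part.
#' @return tibble (block, weight, size, min_re, max_re, max_im,
#'   stiffness_ratio, stable).
#' @export
spectral_check <- function(sys, zero_tol = 1e-10) {
  rows <- lapply(seq_along(sys$blocks), function(b) {
    M <- block_internal_matrix(sys, b)
    ev <- eigen(M, only.values = TRUE)$values
    re <- Re(ev)
    ratio <- if (min(abs(re)) > 1e-12) max(abs(re)) / min(abs(re)) else NA_real_
    tibble(block = b, weight = sys$blocks[[b]]$weight,
           size = sys$blocks[[b]]$nb,
           min_re = min(re), max_re = max(re), max_im = max(abs(Im(ev))),
           stiffness_ratio = ratio,
           stable = max(re) < -zero_tol)
  })
  dplyr::bind_rows(rows)
}

#' Stationary (t -> infinity) mass isotopomer distributions
#'
#' Solves the algebraic EMU balance size class by size class: within one
#' EMU size the unimolecular couplings are linear and the multi-reactant
#' convolutions only involve strictly smaller, already-solved EMUs.
#' Serves as the long-time oracle for the transient integrators.
#'
#' @param network an `emu_network`.
#' @param fluxes named flux vector; defaults to the model's.
#' @param labeling substrate labeling; defaults to the model's.
#' @return named list: EMU key -> stationary MID vector.
#' @export
stationary_solution <- function(network, fluxes = NULL, labeling = NULL) {
  model <- network$model
  if (!is.null(fluxes)) model$fluxes <- fluxes
  if (!is.null(labeling)) model$labeling <- labeling
  cons <- consumption_rates(model)
  mids <- list()
  for (k in network$input_keys) {
    mids[[k]] <- input_emu_mid(model, network$emus[[k]])
  }
  by_size <- emus_by_size(network)
  for (sz in names(by_size)) {
    group <- by_size[[sz]]
    keys <- setdiff(names(group), network$input_keys)
    if (!length(keys)) next
    s <- as.integer(sz)
    nunk <- length(keys) * (s + 1L)
    pos <- function(key, w) (match(key, keys) - 1L) * (s + 1L) + w + 1L
    A <- matrix(0, nunk, nunk)
    rhs <- numeric(nunk)
    for (key in keys) {
      vout <- cons[network$emus[[key]]$metabolite]
      for (w in 0:s) A[pos(key, w), pos(key, w)] <- -vout
    }
    for (r in network$reactions) {
      pk <- emu_key(r$product)
      if (!(pk %in% keys)) next
      v <- model$fluxes[[r$rxn]] * r$weight
      rkeys <- vapply(r$reactants, emu_key, character(1))
      if (length(rkeys) == 1L && rkeys[1] %in% keys) {
        for (w in 0:s) {
          A[pos(pk, w), pos(rkeys[1], w)] <- A[pos(pk, w), pos(rkeys[1], w)] + v
        }
      } else {
        known <- lapply(rkeys, function(k2) {
          m <- mids[[k2]]
          if (is.null(m)) stop("internal: unsolved smaller EMU ", k2,
                               call. = FALSE)
          m
        })
        cc <- Reduce(convolve_mid, known)
        for (w in 0:s) rhs[pos(pk, w)] <- rhs[pos(pk, w)] - v * cc[w + 1]
      }
    }
    sol <- tryCatch(solve(A, rhs), error = function(e) {
      stop("singular stationary balance for EMU size ", sz, " block (",
           paste(keys, collapse = ", "), ")", call. = FALSE)
    })
    for (key in keys) {
      mids[[key]] <- sol[pos(key, 0):pos(key, s)]
    }
  }
  mids[names(network$emus)]
}

#' Brute-force full positional-isotopomer reference
#'
#' Integrates the complete positional isotopomer ODE system (2^n states
#' per intracellular metabolite) with a dense high-accuracy solver and
#' marginalizes to the MID of any requested EMU.  A deliberately
#' independent route from the SCC machinery: it is built directly from
#' the reaction atom maps and solved with `deSolve`.
#'
#' @param model a `metabolic_model` with fluxes, pools and labeling.
#' @param times output times (must start at 0).
#' @param emus list of [emu()] to marginalize onto; defaults to every
#'   non-input EMU of the traced measured network.
#' @param guard maximum total isotopomer count (default 1e4).
#' @param rtol,atol solver tolerances.
#' @return list: EMU key -> matrix (weights 0..n in rows, times in
#'   columns).
#' @export
isotopomer_oracle <- function(model, times, emus = NULL, guard = 1e4,
                              rtol = 1e-11, atol = 1e-11) {
  stopifnot(times[1] == 0)
  carbons <- setNames(model$metabolites$carbons, model$metabolites$id)
  substrates <- names(model$labeling)
  state_mets <- setdiff(
    model$metabolites$id[!model$metabolites$extracellular], substrates)
  n_iso <- sum(2^carbons[state_mets])
  if (n_iso > guard) {
    stop("isotopomer count ", n_iso, " exceeds guard ", guard, call. = FALSE)
  }
  offs <- c(0, cumsum(2^carbons[state_mets]))
  names(offs) <- c(state_mets, "_end")
  idx_of <- function(met, bits) offs[[met]] + sum(bits * 2^(seq_along(bits) - 1)) + 1

  subst_frac <- lapply(substrates, function(m) {
    frac <- setNames(numeric(2^carbons[[m]]), NULL)
    for (i in seq_along(model$labeling[[m]])) {
      bits <- as.integer(strsplit(names(model$labeling[[m]])[i], "")[[1]])
      frac[sum(bits * 2^(seq_along(bits) - 1)) + 1] <-
        frac[sum(bits * 2^(seq_along(bits) - 1)) + 1] + model$labeling[[m]][[i]]
    }
    frac
  })
  names(subst_frac) <- substrates

  bit_patterns <- function(n) {
    m <- as.matrix(expand.grid(rep(list(0:1), n)))
    m[, seq_len(n), drop = FALSE]
  }

  # production terms: (target index, list of state factors / constant)
  terms <- list()
  cons <- consumption_rates(model)
  for (r in model$reactions) {
    v <- model$fluxes[[r$id]]
    if (v == 0) next
    state_prods <- which(r$products %in% state_mets)
    if (!length(state_prods)) next
    for (a in seq_along(r$transitions)) {
      tr <- r$transitions[[a]]
      wfrac <- 1 / length(r$transitions)
      pats <- lapply(seq_along(r$reactants), function(j) {
        bit_patterns(carbons[[r$reactants[j]]])
      })
      combo_grid <- expand.grid(lapply(pats, function(p) seq_len(nrow(p))))
      for (g in seq_len(nrow(combo_grid))) {
        bits_by_letter <- list()
        factors <- list()
        skip <- FALSE
        for (j in seq_along(r$reactants)) {
          bits <- pats[[j]][combo_grid[g, j], ]
          letters_j <- strsplit(tr$reactant_maps[j], "")[[1]]
          for (p2 in seq_along(letters_j)) {
            bits_by_letter[[letters_j[p2]]] <- bits[p2]
          }
          met <- r$reactants[j]
          if (met %in% substrates) {
            prob <- subst_frac[[met]][sum(bits * 2^(seq_along(bits) - 1)) + 1]
            if (prob == 0) { skip <- TRUE; break }
            factors[[length(factors) + 1L]] <- list(const = prob)
          } else if (met %in% state_mets) {
            factors[[length(factors) + 1L]] <- list(idx = idx_of(met, bits))
          } else {
            stop("reactant ", met, " is neither balanced nor labeled",
                 call. = FALSE)
          }
        }
        if (skip) next
        for (o in state_prods) {
          pletters <- strsplit(tr$product_maps[o], "")[[1]]
          pbits <- vapply(pletters, function(L) bits_by_letter[[L]], numeric(1))
          terms[[length(terms) + 1L]] <- list(
            tgt = idx_of(r$products[o], pbits),
            coef = v * wfrac / model$pool_sizes[[r$products[o]]],
            idxs = unlist(lapply(factors, function(f) f$idx)),
            const = prod(unlist(lapply(factors, function(f) f$const)), 1)
          )
        }
      }
    }
  }
  tgt_v <- vapply(terms, `[[`, numeric(1), "tgt")
  coef_v <- vapply(terms, function(tm) tm$coef * tm$const, numeric(1))
  idx_l <- lapply(terms, `[[`, "idxs")
  decay <- numeric(n_iso)
  for (m in state_mets) {
    rng <- (offs[[m]] + 1):(offs[[m]] + 2^carbons[[m]])
    decay[rng] <- cons[m] / model$pool_sizes[[m]]
  }
  deriv <- function(t, y, parms) {
    d <- -decay * y
    prodv <- coef_v
    for (i in seq_along(idx_l)) {
      ii <- idx_l[[i]]
      if (length(ii)) prodv[i] <- prodv[i] * prod(y[ii])
    }
    for (i in seq_along(tgt_v)) d[tgt_v[i]] <- d[tgt_v[i]] + prodv[i]
    list(d)
  }
  y0 <- numeric(n_iso)
  for (m in state_mets) y0[idx_of(m, rep(0, carbons[[m]]))] <- 1
  sol <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  yt <- t(unname(sol[, -1, drop = FALSE]))  # n_iso x n_times

  if (is.null(emus)) {
    network <- trace_emus(model)
    emus <- network$emus[setdiff(names(network$emus), network$input_keys)]
  }
  out <- list()
  for (e in emus) {
    if (!(e$metabolite %in% state_mets)) next
    nc <- carbons[[e$metabolite]]
    pats <- bit_patterns(nc)
    w <- rowSums(pats[, e$atoms, drop = FALSE])
    mid <- matrix(0, e$size + 1L, ncol(yt))
    rng <- (offs[[e$metabolite]] + 1):(offs[[e$metabolite]] + 2^nc)
    for (p2 in seq_len(nrow(pats))) {
      # row order of pats matches idx_of's little-endian bit encoding
      mid[w[p2] + 1L, ] <- mid[w[p2] + 1L, ] + yt[rng[p2], ]
    }
    out[[emu_key(e)]] <- mid
  }
  out
}

#' Conservation report for a trajectory
#'
#' Maximum over time of |sum_w m_w - 1| for every complete EMU in the
#' state, and (for augmented trajectories) of |sum_w dm_w/dtheta| per
#' (EMU, parameter).
#'
#' @param traj an `iso_trajectory`.
#' @return list with tibbles `mid` and `sensitivity` (empty when the
#'   trajectory carries no sensitivities).
#' @export
conservation_report <- function(traj) {
  sys <- traj$sys
  nt <- sys$node_tab
  base <- traj$states[seq_len(sys$nx), , drop = FALSE]
  keys <- unique(nt$emu_key)
  mid_rows <- lapply(keys, function(k) {
    rows <- which(nt$emu_key == k)
    complete <- length(rows) == nt$size[rows[1]] + 1L
    dev <- if (complete) {
      max(abs(colSums(base[rows, , drop = FALSE]) - 1))
    } else NA_real_
    tibble(emu = k, complete = complete, max_deviation = dev)
  })
  mid <- dplyr::bind_rows(mid_rows)
  sens <- tibble(emu = character(0), parameter = character(0),
                 max_deviation = numeric(0))
  if (inherits(sys, "augmented_cascade")) {
    rows_all <- lapply(keys, function(k) which(nt$emu_key == k))
    out <- list()
    for (r in seq_len(sys$npar)) {
      S <- traj$states[r * sys$nx + seq_len(sys$nx), , drop = FALSE]
      for (i in seq_along(keys)) {
        rows <- rows_all[[i]]
        if (length(rows) != nt$size[rows[1]] + 1L) next
        out[[length(out) + 1L]] <- tibble(
          emu = keys[i], parameter = sys$par_names[r],
          max_deviation = max(abs(colSums(S[rows, , drop = FALSE]))))
      }
    }
    if (length(out)) sens <- dplyr::bind_rows(out)
  }
  list(mid = mid, sensitivity = sens)
}
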
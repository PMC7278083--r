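# Assembly of the per-SCC isotope balance ODEs.
#
# For every SCC block the right-hand side is
#
#   C dx/dt =  sum_p v_p Q_p (x_parents ...)      production, 0/1 tensor Q
#            + sum_c v_c E_c x                    consumption, diagonal E
#            + sum_inp v_inp Q_inp x_inp          constant substrate input
#
# with the diagonal pool-size matrix C inverted once at assembly time and
# folded into every coefficient.  Two evaluation backends are built from
# the same term set: "tensor" contracts sparse coordinate entries of Q
# composition by composition; "vector" applies the linear M matrices as a
# sparse matrix-vector product and evaluates multi-reactant reactions
# through the full MID convolution restricted to the mass isotopomers
# present in the target SCC.

#' Convolution of two mass isotopomer distributions
#'
#' `c_w = sum_{u+v=w} a_u b_v` — the MID of a fragment formed by joining
#' two independent fragments.
#'
#' @param a,b non-negative numeric vectors (weights 0..n).
#' @export
convolve_mid <- function(a, b) {
  stopifnot(all(a >= 0), all(b >= 0))
  conv_raw(a, b)
}

# unchecked kernel: integrator stage states may carry harmless tiny
# negative round-off
conv_raw <- function(a, b) {
  n <- length(a) + length(b) - 1L
  out <- numeric(n)
  for (u in seq_along(a)) {
    idx <- u:(u + length(b) - 1L)
    out[idx] <- out[idx] + a[u] * b
  }
  out
}

#' Weight-composition transition tensor of an EMU reaction
#'
#' Sparse 0/1 tensor in coordinate form: one row per reactant weight
#' tuple, with the product weight it composes to.  For any fixed reactant
#' tuple exactly one product index carries a 1.
#'
#' @param reaction an EMU reaction (element of `emu_network$reactions`).
#' @return tibble with columns `i1..in` (reactant weights) and `j`
#'   (product weight), all 0-based.
#' @export
build_transition_tensor <- function(reaction) {
  sizes <- vapply(reaction$reactants, `[[`, integer(1), "size")
  rows <- list()
  for (w in 0:reaction$product$size) {
    comps <- weight_compositions(sizes, w)
    if (nrow(comps)) rows[[length(rows) + 1L]] <- cbind(comps, j = w)
  }
  m <- do.call(rbind, rows)
  colnames(m) <- c(paste0("i", seq_along(sizes)), "j")
  as_tibble(as.data.frame(m))
}

#' Eliminating matrix of a reaction acting on an SCC block
#'
#' Diagonal matrix with -1 where the reaction consumes the metabolite of
#' the block's mass isotopomer and 0 elsewhere.
#'
#' @param block_metabolites metabolite id per block element.
#' @param consumed metabolite ids the reaction consumes.
#' @export
build_eliminating_matrix <- function(block_metabolites, consumed) {
  d <- ifelse(block_metabolites %in% consumed, -1, 0)
  diag(d, nrow = length(d))
}

#' Assemble the cascade ODE system for a sorted SCC partition
#'
#' @param partition a sorted (optionally lambda-aggregated)
#'   `scc_partition` of a pruned graph.
#' @param model the `metabolic_model` supplying fluxes and pool sizes.
#' @param backend `"vector"` (default; M-matrix products plus restricted
#'   convolution) or `"tensor"` (coordinate contraction of the transition
#'   tensors).  Both are assembled; the flag picks the evaluation route.
#' @return a `cascade_system`.
#' @export
assemble_cascade <- function(partition, model, backend = c("vector", "tensor")) {
  backend <- match.arg(backend)
  stopifnot(isTRUE(partition$sorted))
  graph <- partition$graph
  network <- graph$network
  rxn_ids <- vapply(network$reactions, `[[`, character(1), "rxn")
  fluxvec <- vapply(rxn_ids, function(id) {
    v <- model$fluxes[id]
    if (is.na(v)) stop("no flux value for reaction ", id, call. = FALSE)
    unname(v)
  }, numeric(1))

  # state node table: blocks in topological order, members sorted
  blocks_members <- lapply(partition$sccs, `[[`, "members")
  keys <- unlist(blocks_members)
  ninfo <- graph$nodes[match(keys, graph$nodes$key), ]
  nx <- length(keys)
  node_tab <- tibble(
    key = keys,
    emu_key = ninfo$emu_key,
    metabolite = ninfo$metabolite,
    weight = ninfo$weight,
    size = ninfo$size,
    block = rep(seq_along(blocks_members),
                vapply(blocks_members, length, integer(1))),
    idx = seq_len(nx)
  )
  state_idx <- setNames(node_tab$idx, node_tab$key)

  # pool sizes per node (error if missing for a pruned-network metabolite)
  mets <- unique(node_tab$metabolite)
  missing_pool <- mets[!(mets %in% names(model$pool_sizes))]
  if (length(missing_pool)) {
    stop("missing pool size for metabolite(s): ",
         paste(missing_pool, collapse = ", "), call. = FALSE)
  }
  pool <- unname(model$pool_sizes[node_tab$metabolite])

  # constant input nodes: every (input EMU, weight) of the traced network
  in_keys <- network$input_keys
  ext_keys <- character(0); ext_values <- numeric(0)
  for (k in in_keys) {
    e <- network$emus[[k]]
    mid <- input_emu_mid(model, e)
    ext_keys <- c(ext_keys, node_key(k, 0:e$size))
    ext_values <- c(ext_values, mid)
  }
  ext_idx <- setNames(nx + seq_along(ext_keys), ext_keys)
  K <- length(ext_keys)

  lookup <- function(key) {
    i <- state_idx[key]
    if (!is.na(i)) return(unname(i))
    j <- ext_idx[key]
    if (!is.na(j)) return(unname(j))
    NA_integer_
  }

  # --- production terms -------------------------------------------------
  lin <- list(t = integer(0), s = integer(0), unit = numeric(0),
              rxn = integer(0), multi = logical(0))
  cst <- list(t = integer(0), base = numeric(0), rxn = integer(0),
              multi = logical(0))
  bl <- list(t = integer(0), s1 = integer(0), s2 = integer(0),
             unit = numeric(0), rxn = integer(0))
  nary <- list()
  conv <- list()

  for (q in seq_along(network$reactions)) {
    r <- network$reactions[[q]]
    narg <- length(r$reactants)
    rkeys <- vapply(r$reactants, emu_key, character(1))
    rsizes <- vapply(r$reactants, `[[`, integer(1), "size")
    pk <- emu_key(r$product)
    present_w <- node_tab$weight[node_tab$emu_key == pk]
    if (!length(present_w)) next
    for (w in present_w) {
      tgt <- unname(state_idx[node_key(pk, w)])
      unit0 <- r$weight / pool[tgt]
      comps <- weight_compositions(rsizes, w)
      for (ci in seq_len(nrow(comps))) {
        srcs <- vapply(seq_len(narg), function(k) {
          lookup(node_key(rkeys[k], comps[ci, k]))
        }, integer(1))
        if (anyNA(srcs)) {
          stop("internal: reactant node missing for present product node",
               call. = FALSE)
        }
        is_state <- srcs <= nx
        ext_factor <- prod(ext_values[srcs[!is_state] - nx])
        ssrc <- srcs[is_state]
        ns <- length(ssrc)
        if (ns == 0L) {
          cst$t <- c(cst$t, tgt); cst$base <- c(cst$base, unit0 * ext_factor)
          cst$rxn <- c(cst$rxn, q); cst$multi <- c(cst$multi, narg > 1L)
        } else if (ns == 1L) {
          lin$t <- c(lin$t, tgt); lin$s <- c(lin$s, ssrc)
          lin$unit <- c(lin$unit, unit0 * ext_factor)
          lin$rxn <- c(lin$rxn, q); lin$multi <- c(lin$multi, narg > 1L)
        } else if (ns == 2L) {
          bl$t <- c(bl$t, tgt)
          bl$s1 <- c(bl$s1, ssrc[1]); bl$s2 <- c(bl$s2, ssrc[2])
          bl$unit <- c(bl$unit, unit0 * ext_factor)
          bl$rxn <- c(bl$rxn, q)
        } else {
          nary[[length(nary) + 1L]] <- list(t = tgt, srcs = ssrc,
                                            unit = unit0 * ext_factor, rxn = q)
        }
      }
    }
    # convolution route for every multi-reactant reaction (vector backend)
    if (narg >= 2L) {
      gathers <- lapply(seq_len(narg), function(k) {
        vapply(0:rsizes[k], function(wk) lookup(node_key(rkeys[k], wk)),
               integer(1))
      })
      for (b in unique(node_tab$block[node_tab$emu_key == pk])) {
        rows <- node_tab[node_tab$emu_key == pk & node_tab$block == b, ]
        conv[[length(conv) + 1L]] <- list(
          block = b, rxn = q, srcs = gathers,
          tgt_local = match(rows$key, blocks_members[[b]]),
          tgt_w = rows$weight,
          unit = r$weight / unname(model$pool_sizes[rows$metabolite]),
          prod_size = r$product$size
        )
      }
    }
  }

  # --- consumption (eliminating) terms ---------------------------------
  cons_by_met <- setNames(lapply(mets, function(m) {
    hits <- integer(0)
    for (q2 in seq_along(model$reactions)) {
      mult <- sum(model$reactions[[q2]]$reactants == m)
      if (mult > 0) hits <- c(hits, rep(q2, mult))
    }
    hits
  }), mets)
  # map model reaction index -> network flux index space: consumption uses
  # model reactions directly, so extend fluxvec with one entry per model
  # reaction after the network's EMU reactions.
  model_ids <- vapply(model$reactions, `[[`, character(1), "id")
  cons_fluxvec <- vapply(model_ids, function(id) {
    v <- model$fluxes[id]
    if (is.na(v)) stop("no flux value for reaction ", id, call. = FALSE)
    unname(v)
  }, numeric(1))
  n_emu_rxn <- length(network$reactions)
  fluxvec_all <- c(fluxvec, cons_fluxvec)
  rxn_of_term <- function(model_q) n_emu_rxn + model_q
  for (i in seq_len(nx)) {
    m <- node_tab$metabolite[i]
    for (q2 in cons_by_met[[m]]) {
      lin$t <- c(lin$t, i); lin$s <- c(lin$s, i)
      lin$unit <- c(lin$unit, -1 / pool[i])
      lin$rxn <- c(lin$rxn, rxn_of_term(q2)); lin$multi <- c(lin$multi, FALSE)
    }
  }

  # reaction id per flux index (EMU reactions then model reactions)
  flux_rxn_id <- c(rxn_ids, model_ids)

  # --- per-block structures --------------------------------------------
  nb_list <- vapply(blocks_members, length, integer(1))
  blocks <- vector("list", length(blocks_members))
  lin_t_block <- node_tab$block[lin$t]
  cst_t_block <- node_tab$block[cst$t]
  bl_t_block <- node_tab$block[bl$t]
  ncols <- nx + K
  for (b in seq_along(blocks)) {
    rows <- which(node_tab$block == b)
    nb <- length(rows)
    loc <- integer(nx); loc[rows] <- seq_len(nb)
    li <- which(lin_t_block == b)
    Lb <- sparseMatrix(i = loc[lin$t[li]], j = lin$s[li],
                       x = lin$unit[li] * fluxvec_all[lin$rxn[li]],
                       dims = c(nb, ncols))
    lv <- li[!lin$multi[li]]
    Lb_v <- sparseMatrix(i = loc[lin$t[lv]], j = lin$s[lv],
                         x = lin$unit[lv] * fluxvec_all[lin$rxn[lv]],
                         dims = c(nb, ncols))
    ci <- which(cst_t_block == b)
    bb <- numeric(nb)
    for (k in ci) bb[loc[cst$t[k]]] <- bb[loc[cst$t[k]]] +
      cst$base[k] * fluxvec_all[cst$rxn[k]]
    cv <- ci[!cst$multi[ci]]
    bb_v <- numeric(nb)
    for (k in cv) bb_v[loc[cst$t[k]]] <- bb_v[loc[cst$t[k]]] +
      cst$base[k] * fluxvec_all[cst$rxn[k]]
    bi <- which(bl_t_block == b)
    Ab <- sparseMatrix(i = loc[bl$t[bi]], j = seq_along(bi), x = 1,
                       dims = c(nb, length(bi)))
    nary_b <- Filter(function(tm) node_tab$block[tm$t] == b, nary)
    nary_b <- lapply(nary_b, function(tm) {
      tm$t_local <- loc[tm$t]
      tm$coef <- tm$unit * fluxvec_all[tm$rxn]
      tm
    })
    conv_b <- Filter(function(cc) cc$block == b, conv)
    conv_b <- lapply(conv_b, function(cc) {
      cc$Sc <- sparseMatrix(i = cc$tgt_local, j = cc$tgt_w + 1L,
                            x = cc$unit * fluxvec_all[cc$rxn],
                            dims = c(nb, cc$prod_size + 1L))
      cc
    })
    src_blocks <- function(ix) {
      ix <- ix[!is.na(ix) & ix <= nx]
      unique(node_tab$block[ix])
    }
    deps <- unique(c(
      src_blocks(lin$s[li]),
      src_blocks(c(bl$s1[bi], bl$s2[bi])),
      unlist(lapply(nary_b, function(tm) src_blocks(tm$srcs))),
      unlist(lapply(conv_b, function(cc) src_blocks(unlist(cc$srcs))))
    ))
    blocks[[b]] <- list(
      idx = rows, nb = nb, weight = partition$sccs[[b]]$weight,
      Lb = Lb, Lb_v = Lb_v, bb = bb, bb_v = bb_v,
      bl = list(t_local = loc[bl$t[bi]], s1 = bl$s1[bi], s2 = bl$s2[bi],
                unit = bl$unit[bi], rxn = bl$rxn[bi],
                coef = bl$unit[bi] * fluxvec_all[bl$rxn[bi]]),
      Ab = Ab,
      nary = nary_b,
      conv = conv_b,
      meta = list(lin = lapply(lin, `[`, li), cst = lapply(cst, `[`, ci)),
      loc = loc,
      deps = sort(deps)
    )
  }

  sys <- structure(list(
    node_tab = node_tab, nx = nx,
    ext_keys = ext_keys, ext_values = ext_values,
    pool = pool,
    blocks = blocks,
    backend = backend,
    fluxvec_all = fluxvec_all,
    flux_rxn_id = flux_rxn_id,
    partition = partition, model = model, network = network
  ), class = "cascade_system")
  # Gershgorin bound on the fastest relaxation rate across SCC blocks;
  # explicit steppers are stable only below ~2.8/rate, and the adaptive
  # broadcast step is capped there (the m0 pilot cannot observe
  # instability of heavier isotopomers of the same pool)
  sys$rate_bound <- max(vapply(seq_along(blocks), function(b) {
    M <- block_internal_matrix(sys, b)
    if (!nrow(M)) return(0)
    max(rowSums(abs(M)))
  }, numeric(1)), 0)
  sys
}

#' @export
print.cascade_system <- function(x, ...) {
  cat("<cascade_system> ", x$nx, " mass isotopomer states in ",
      length(x$blocks), " SCC blocks (backend: ", x$backend, ")\n", sep = "")
  invisible(x)
}

gather_mid <- function(xa, idx) {
  v <- xa[idx]
  v[is.na(idx)] <- 0
  v
}

# Right-hand side of one SCC block, reading only the block itself, its
# ancestor blocks and the constant substrate values.
rhs_block <- function(sys, b, xa, backend = sys$backend) {
  bl <- sys$blocks[[b]]
  if (backend == "vector") {
    d <- as.numeric(bl$Lb_v %*% xa) + bl$bb_v
    for (cc in bl$conv) {
      mids <- lapply(cc$srcs, function(ix) gather_mid(xa, ix))
      m <- Reduce(conv_raw, mids)
      d <- d + as.numeric(cc$Sc %*% m)
    }
  } else {
    d <- as.numeric(bl$Lb %*% xa) + bl$bb
    if (length(bl$bl$t_local)) {
      d <- d + as.numeric(bl$Ab %*% (bl$bl$coef * xa[bl$bl$s1] * xa[bl$bl$s2]))
    }
    for (tm in bl$nary) {
      d[tm$t_local] <- d[tm$t_local] + tm$coef * prod(xa[tm$srcs])
    }
  }
  d
}

#' Evaluate the cascade right-hand side
#'
#' @param sys a `cascade_system` (or augmented system).
#' @param state numeric state vector.
#' @param t time (the system is autonomous; accepted for interface
#'   compatibility).
#' @param backend optionally override the assembly-time backend.
#' @export
cascade_rhs <- function(sys, state, t = 0, backend = sys$backend) {
  UseMethod("cascade_rhs")
}

#' @export
cascade_rhs.cascade_system <- function(sys, state, t = 0,
                                       backend = sys$backend) {
  stopifnot(length(state) == sys$nx)
  xa <- c(state, sys$ext_values)
  out <- numeric(sys$nx)
  for (b in seq_along(sys$blocks)) {
    out[sys$blocks[[b]]$idx] <- rhs_block(sys, b, xa, backend)
  }
  out
}

#' Initial state of a cascade system
#'
#' Unlabeled steady state: `m0 = 1` for every EMU, heavier mass
#' isotopomers 0.  Sensitivity blocks of an augmented system start at 0.
#'
#' @param sys a `cascade_system`.
#' @export
initial_state <- function(sys) {
  UseMethod("initial_state")
}

#' @export
initial_state.cascade_system <- function(sys) {
  as.numeric(sys$node_tab$weight == 0L)
}

#' Serialize an assembled system to a JSON bundle
#'
#' Sparse matrices are written as triplet lists for inspection and
#' reload with [read_cascade_json()].
#'
#' @param sys a `cascade_system`.
#' @param path output path.
#' @export
write_cascade_json <- function(sys, path) {
  trip <- function(M) {
    tm <- methods::as(M, "TsparseMatrix")
    list(i = tm@i + 1L, j = tm@j + 1L, x = tm@x, dim = dim(M))
  }
  payload <- list(
    nodes = as.data.frame(sys$node_tab),
    ext = list(keys = sys$ext_keys, values = sys$ext_values),
    blocks = lapply(sys$blocks, function(b) {
      list(idx = b$idx, weight = b$weight, L = trip(b$Lb), b = b$bb,
           bilinear = b$bl[c("t_local", "s1", "s2", "coef")],
           deps = b$deps)
    }),
    backend = sys$backend
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
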
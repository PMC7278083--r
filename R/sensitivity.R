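# Forward sensitivities over free fluxes and pool sizes.
#
# Differentiating the cascade ODE C dx/dt = g(x; v, C) with respect to a
# parameter theta gives d(dx/dtheta)/dt = J(x) dx/dtheta + df/dtheta,
# evaluated blockwise along the same cascade.  Flux directions enter
# through the null-space basis N (v = v0 + N u); pool-size directions
# differentiate the folded C^-1, giving df/dC_m = -f * 1[met = m] / C_m
# because every right-hand-side row carries exactly one 1/C factor.
# Sensitivity initial conditions are zero.

#' Free-flux and pool-size parameterization
#'
#' @param model a `metabolic_model`.
#' @param pruned_metabolites metabolites of the pruned mass isotopomer
#'   network; pool parameters are restricted to these.  Defaults to all
#'   intracellular metabolites.
#' @return a `parameterization`: orthonormal null-space basis `N` (rows
#'   named by reaction) and the free pool list.
#' @export
build_parameterization <- function(model, pruned_metabolites = NULL) {
  d <- free_flux_dimension(model)
  if (d == 0) stop("fluxes fully determined: zero-dimensional null space",
                   call. = FALSE)
  N <- attr(d, "basis")
  intracell <- model$metabolites$id[!model$metabolites$extracellular]
  pools <- if (is.null(pruned_metabolites)) intracell else
    intersect(intracell, unique(pruned_metabolites))
  structure(list(N = N, n_free_fluxes = as.integer(d),
                 free_pools = sort(pools)),
            class = "parameterization")
}

#' @export
print.parameterization <- function(x, ...) {
  cat("<parameterization> ", x$n_free_fluxes, " free fluxes, ",
      length(x$free_pools), " free pool sizes\n", sep = "")
  invisible(x)
}

#' Extend a cascade system with forward sensitivity equations
#'
#' The augmented state is `c(x, dx/du_1, ..., dx/dC_m, ...)`; every
#' sensitivity block shares the SCC block structure (and, in adaptive
#' mode, the step size) of the base state.
#'
#' @param sys a `cascade_system`.
#' @param params a `parameterization`; defaults to one built from the
#'   system's model and pruned metabolites.
#' @return an `augmented_cascade` system usable with the same
#'   integrators.
#' @export
extend_with_sensitivities <- function(sys, params = NULL) {
  if (inherits(sys, "augmented_cascade")) return(sys)
  if (is.null(params)) {
    params <- build_parameterization(sys$model,
                                     unique(sys$node_tab$metabolite))
  }
  N <- params$N
  nflux <- ncol(N)
  pools <- params$free_pools
  npool <- length(pools)
  npar <- nflux + npool
  par_names <- c(paste0("u", seq_len(nflux)), paste0("pool:", pools))
  # derivative of each folded flux term with respect to each free flux
  dv <- N[sys$flux_rxn_id, , drop = FALSE]   # (n_flux_terms x nflux)

  nx <- sys$nx
  ncols <- nx + length(sys$ext_keys)
  blocks_sens <- vector("list", length(sys$blocks))
  for (b in seq_along(sys$blocks)) {
    bl <- sys$blocks[[b]]
    li <- bl$meta$lin; ci <- bl$meta$cst
    loc <- bl$loc
    per_flux <- lapply(seq_len(nflux), function(r) {
      Lb_r <- sparseMatrix(i = loc[li$t], j = li$s,
                           x = li$unit * dv[li$rxn, r],
                           dims = c(bl$nb, ncols))
      bb_r <- numeric(bl$nb)
      for (k in seq_along(ci$t)) {
        bb_r[loc[ci$t[k]]] <- bb_r[loc[ci$t[k]]] + ci$base[k] * dv[ci$rxn[k], r]
      }
      bl_coef_r <- bl$bl$unit * dv[bl$bl$rxn, r]
      nary_r <- vapply(bl$nary, function(tm) tm$unit * dv[tm$rxn, r],
                       numeric(1))
      list(Lb = Lb_r, bb = bb_r, bl_coef = bl_coef_r, nary_coef = nary_r)
    })
    pool_masks <- lapply(pools, function(m) {
      which(sys$node_tab$metabolite[bl$idx] == m)
    })
    blocks_sens[[b]] <- list(per_flux = per_flux, pool_masks = pool_masks)
  }
  out <- sys
  out$params <- params
  out$npar <- npar
  out$par_names <- par_names
  out$nflux <- nflux
  out$pool_params <- pools
  out$pool_values <- unname(sys$model$pool_sizes[pools])
  out$blocks_sens <- blocks_sens
  class(out) <- c("augmented_cascade", "cascade_system")
  out
}

#' @export
print.augmented_cascade <- function(x, ...) {
  cat("<augmented_cascade> ", x$nx, " states x (1 + ", x$npar,
      " sensitivity directions) in ", length(x$blocks), " SCC blocks\n",
      sep = "")
  invisible(x)
}

n_total <- function(sys) {
  if (inherits(sys, "augmented_cascade")) sys$nx * (1L + sys$npar) else sys$nx
}

block_rows <- function(sys, b) {
  idx <- sys$blocks[[b]]$idx
  if (!inherits(sys, "augmented_cascade")) return(idx)
  c(idx, as.vector(outer(idx, seq_len(sys$npar) * sys$nx, `+`)))
}

# Directional derivative of the production terms along state direction s
# (tensor view), plus the linear/consumption part: J %*% s for one block.
jacobian_product_block <- function(sys, b, xa, sa) {
  bl <- sys$blocks[[b]]
  d <- as.numeric(bl$Lb %*% sa)
  if (length(bl$bl$t_local)) {
    d <- d + as.numeric(bl$Ab %*% (bl$bl$coef *
                                     (xa[bl$bl$s1] * sa[bl$bl$s2] +
                                        sa[bl$bl$s1] * xa[bl$bl$s2])))
  }
  for (tm in bl$nary) {
    xs <- xa[tm$srcs]; ss <- sa[tm$srcs]
    acc <- 0
    for (k in seq_along(tm$srcs)) {
      acc <- acc + prod(xs[-k]) * ss[k]
    }
    d[tm$t_local] <- d[tm$t_local] + tm$coef * acc
  }
  d
}

# Forcing term df/du_r for one block (everything flux-linear).
flux_forcing_block <- function(sys, b, r, xa) {
  bl <- sys$blocks[[b]]
  pf <- sys$blocks_sens[[b]]$per_flux[[r]]
  d <- as.numeric(pf$Lb %*% xa) + pf$bb
  if (length(bl$bl$t_local)) {
    d <- d + as.numeric(bl$Ab %*% (pf$bl_coef * xa[bl$bl$s1] * xa[bl$bl$s2]))
  }
  for (k in seq_along(bl$nary)) {
    tm <- bl$nary[[k]]
    d[tm$t_local] <- d[tm$t_local] + pf$nary_coef[k] * prod(xa[tm$srcs])
  }
  d
}

# Per-block augmented derivative: c(f_b, sensitivity rows).
aug_rhs_block <- function(sys, b, xa, S_ext) {
  f_b <- rhs_block(sys, b, xa)
  nb <- sys$blocks[[b]]$nb
  out <- numeric(nb * (1L + sys$npar))
  out[seq_len(nb)] <- f_b
  pos <- nb
  for (r in seq_len(sys$nflux)) {
    d <- jacobian_product_block(sys, b, xa, S_ext[, r]) +
      flux_forcing_block(sys, b, r, xa)
    out[pos + seq_len(nb)] <- d
    pos <- pos + nb
  }
  for (p in seq_along(sys$pool_params)) {
    r <- sys$nflux + p
    d <- jacobian_product_block(sys, b, xa, S_ext[, r])
    mask <- sys$blocks_sens[[b]]$pool_masks[[p]]
    if (length(mask)) d[mask] <- d[mask] - f_b[mask] / sys$pool_values[p]
    out[pos + seq_len(nb)] <- d
    pos <- pos + nb
  }
  out
}

#' @export
cascade_rhs.augmented_cascade <- function(sys, state, t = 0,
                                          backend = sys$backend) {
  nx <- sys$nx; npar <- sys$npar
  stopifnot(length(state) == nx * (1 + npar))
  x <- state[seq_len(nx)]
  S <- matrix(state[-seq_len(nx)], nx, npar)
  xa <- c(x, sys$ext_values)
  S_ext <- rbind(S, matrix(0, length(sys$ext_values), npar))
  out <- numeric(length(state))
  for (b in seq_along(sys$blocks)) {
    out[block_rows(sys, b)] <- aug_rhs_block(sys, b, xa, S_ext)
  }
  out
}

#' @export
initial_state.augmented_cascade <- function(sys) {
  c(as.numeric(sys$node_tab$weight == 0L), numeric(sys$nx * sys$npar))
}

# Unified per-block evaluation on a (possibly partially filled) full
# state vector; used by the parallel scheduler.
rhs_block_y <- function(sys, b, y) {
  if (inherits(sys, "augmented_cascade")) {
    nx <- sys$nx
    x <- y[seq_len(nx)]
    S <- matrix(y[-seq_len(nx)], nx, sys$npar)
    aug_rhs_block(sys, b, c(x, sys$ext_values),
                  rbind(S, matrix(0, length(sys$ext_values), sys$npar)))
  } else {
    rhs_block(sys, b, c(y, sys$ext_values))
  }
}
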
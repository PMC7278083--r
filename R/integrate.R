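# Time integration of the cascade ODEs.
#
# Constant-step integration uses the classical explicit 4th-order
# Runge-Kutta tableau (weights (1,2,2,1)/6, stages at t, t+h/2, t+h/2,
# t+h); every SCC block evaluates each stage against its parents' values
# advanced by the same stage increment, so the cascade integrator equals
# RK4 on the monolithic system.  Adaptive stepping uses the embedded
# Cash-Karp 4(5) pair with the per-component tolerance
# tol_scaling * |y| + tol_addition, the step being chosen on a small
# "pilot" m0 subsystem covering every metabolite and then broadcast to
# all SCC blocks.

# Strip sensitivity extensions, keeping the base cascade.
base_system <- function(sys) {
  if (!inherits(sys, "augmented_cascade")) return(sys)
  out <- sys
  class(out) <- "cascade_system"
  out
}

# Restriction of a base cascade system to the first p blocks of the
# topological order (a prefix is ancestor-closed, so the restriction is a
# closed subsystem; convolution gathers that reach outside the prefix can
# only touch weights that never feed a prefix node and are masked out).
subsystem_prefix <- function(sys, p) {
  sys <- base_system(sys)
  if (p >= length(sys$blocks)) return(sys)
  nxp <- sum(vapply(sys$blocks[seq_len(p)], `[[`, integer(1), "nb"))
  nx <- sys$nx
  K <- length(sys$ext_keys)
  colkeep <- c(seq_len(nxp), nx + seq_len(K))
  remap <- function(ix) {
    out <- ix
    out[!is.na(ix) & ix > nxp & ix <= nx] <- NA_integer_
    shift <- !is.na(out) & out > nx
    out[shift] <- out[shift] - (nx - nxp)
    out
  }
  out <- sys
  out$nx <- nxp
  out$node_tab <- sys$node_tab[seq_len(nxp), ]
  out$pool <- sys$pool[seq_len(nxp)]
  out$blocks <- lapply(sys$blocks[seq_len(p)], function(bl) {
    bl$Lb <- bl$Lb[, colkeep, drop = FALSE]
    bl$Lb_v <- bl$Lb_v[, colkeep, drop = FALSE]
    bl$conv <- lapply(bl$conv, function(cc) {
      cc$srcs <- lapply(cc$srcs, remap)
      cc
    })
    bl$meta$lin$s <- remap(bl$meta$lin$s)
    bl
  })
  out
}

#' Pilot node set for adaptive step-size control
#'
#' The smallest prefix of the topological SCC order whose blocks cover at
#' least one EMU of every metabolite of the pruned network, restricted to
#' weight-0 mass isotopomers; a metabolite without any weight-0 node
#' contributes its lightest present node instead.  The step size computed
#' on this subsystem is delivered unchanged to all SCC blocks.
#'
#' @param sys a `cascade_system`.
#' @return list with `blocks` (prefix indices), `node_idx` (state indices
#'   the error is measured on) and `node_keys`.
#' @export
pilot_nodes <- function(sys) {
  nt <- sys$node_tab
  mets <- unique(nt$metabolite)
  chosen <- integer(0)
  need_block <- integer(0)
  for (m in mets) {
    rows <- which(nt$metabolite == m & nt$weight == 0L)
    if (!length(rows)) {
      cand <- which(nt$metabolite == m)
      rows <- cand[which.min(nt$weight[cand])]
    }
    pick <- rows[which.min(nt$block[rows])]
    chosen <- c(chosen, pick)
    need_block <- c(need_block, nt$block[pick])
  }
  p <- max(need_block)
  keep <- nt$weight == 0L & nt$block <= p
  node_idx <- sort(unique(c(which(keep), chosen)))
  list(blocks = seq_len(p), node_idx = node_idx, node_keys = nt$key[node_idx])
}

#' One classical fourth-order Runge-Kutta step
#'
#' @param sys a `cascade_system` (plain or augmented).
#' @param state state vector at time `t`.
#' @param t current time.
#' @param h step size (> 0).
#' @export
rk4_step <- function(sys, state, t, h) {
  stopifnot(h > 0)
  step_with_tableau(sys, state, t, h, rk4_tableau)$state
}

ck_tableau <- list(
  a = list(
    c(1 / 5),
    c(3 / 40, 9 / 40),
    c(3 / 10, -9 / 10, 6 / 5),
    c(-11 / 54, 5 / 2, -70 / 27, 35 / 27),
    c(1631 / 55296, 175 / 512, 575 / 13824, 44275 / 110592, 253 / 4096)
  ),
  b5 = c(37 / 378, 0, 250 / 621, 125 / 594, 0, 512 / 1771),
  b4 = c(2825 / 27648, 0, 18575 / 48384, 13525 / 55296, 277 / 14336, 1 / 4)
)

#' One embedded Cash-Karp 4(5) step
#'
#' @inheritParams rk4_step
#' @return list with `state` (5th-order solution) and `err`
#'   (per-component difference between the embedded 4th- and 5th-order
#'   solutions).
#' @export
cash_karp_step <- function(sys, state, t, h) {
  stopifnot(h > 0)
  step_with_tableau(sys, state, t, h, ck_full_tableau)
}

new_trajectory <- function(sys, times, h, states, mode,
                           n_accept = length(h), n_reject = 0L) {
  structure(list(times = times, h = h, states = states, sys = sys,
                 mode = mode, n_accept = n_accept, n_reject = n_reject),
            class = "iso_trajectory")
}

#' Constant-step RK4 integration over [0, t_end]
#'
#' @param sys a `cascade_system` (plain or augmented).
#' @param step step size; defaults to the model's `settings$step`.
#' @param t_end end time; defaults to `settings$t_end`.
#' @param y0 initial state; defaults to [initial_state()].
#' @return an `iso_trajectory` recording every step.
#' @export
integrate_constant <- function(sys, step = NULL, t_end = NULL, y0 = NULL) {
  step <- step %||% sys$model$settings$step
  t_end <- t_end %||% sys$model$settings$t_end
  stopifnot(step > 0, step <= t_end)
  if (sys$rate_bound > 0 && step * sys$rate_bound > 2.5) {
    warning("step ", step, " exceeds the explicit stability bound ",
            signif(2.5 / sys$rate_bound, 3),
            " for the fastest SCC block; expect amplified round-off",
            call. = FALSE)
  }
  y <- y0 %||% initial_state(sys)
  nfull <- floor(t_end / step + 1e-9)
  hs <- rep(step, nfull)
  if (t_end - nfull * step > 1e-12 * t_end) hs <- c(hs, t_end - nfull * step)
  states <- matrix(NA_real_, length(y), length(hs) + 1L)
  states[, 1] <- y
  t <- 0
  for (k in seq_along(hs)) {
    y <- rk4_step(sys, y, t, hs[k])
    t <- t + hs[k]
    states[, k + 1L] <- y
  }
  new_trajectory(sys, times = c(0, cumsum(hs)), h = hs, states = states,
                 mode = "constant")
}

#' Step controller settings for adaptive integration
#'
#' @param tol_scaling relative tolerance factor (default from the model).
#' @param tol_addition absolute tolerance addition (default from model).
#' @param safety safety factor on the step-size update.
#' @param h_init initial step.
#' @param h_min,h_max step bounds.
#' @export
step_controller <- function(tol_scaling = 1e-9, tol_addition = 1e-7,
                            safety = 0.9, h_init = NULL,
                            h_min = 1e-12, h_max = Inf) {
  list(tol_scaling = tol_scaling, tol_addition = tol_addition,
       safety = safety, h_init = h_init, h_min = h_min, h_max = h_max)
}

#' Adaptive Cash-Karp integration with the pilot step-size controller
#'
#' Each proposed step is tried on the pilot subsystem ([pilot_nodes()]);
#' acceptance is decided there (no downstream rollback), and the accepted
#' step size is applied to the full cascade as a constant-step update.
#' Accepted steps grow by the standard `err^(-1/5)` rule, rejected steps
#' shrink by `err^(-1/4)`.
#'
#' @param sys a `cascade_system` (plain or augmented; sensitivity blocks
#'   share the pilot step size).
#' @param t_end end time; defaults to the model's `settings$t_end`.
#' @param controller a [step_controller()]; tolerance factors default to
#'   the model settings.
#' @param y0 initial state.
#' @return an `iso_trajectory` with per-step sizes and rejection counts.
#' @export
integrate_adaptive <- function(sys, t_end = NULL, controller = NULL,
                               y0 = NULL) {
  t_end <- t_end %||% sys$model$settings$t_end
  st <- sys$model$settings
  ctl <- controller %||% step_controller(tol_scaling = st$tol_scaling,
                                         tol_addition = st$tol_addition)
  ctl$h_init <- ctl$h_init %||% st$step
  ctl$h_max <- min(ctl$h_max, t_end / 10)
  if (sys$rate_bound > 0) ctl$h_max <- min(ctl$h_max, 2.5 / sys$rate_bound)
  pil <- pilot_nodes(base_system(sys))
  psys <- subsystem_prefix(sys, max(pil$blocks))
  pidx <- pil$node_idx

  y <- y0 %||% initial_state(sys)
  t <- 0
  h <- min(ctl$h_init, ctl$h_max)
  times <- 0
  hs <- numeric(0)
  states <- list(y)
  n_reject <- 0L
  while (t < t_end - 1e-12 * t_end) {
    hstep <- min(h, t_end - t)
    yp <- y[seq_len(psys$nx)]
    trial <- cash_karp_step(psys, yp, t, hstep)
    tol <- ctl$tol_scaling * abs(trial$state[pidx]) + ctl$tol_addition
    ratio <- max(abs(trial$err[pidx]) / tol)
    if (ratio <= 1) {
      y <- cash_karp_step(sys, y, t, hstep)$state
      t <- t + hstep
      times <- c(times, t)
      hs <- c(hs, hstep)
      states[[length(states) + 1L]] <- y
      grow <- if (ratio > 0) ctl$safety * ratio^(-1 / 5) else 5
      h <- min(hstep * min(5, grow), ctl$h_max)
    } else {
      n_reject <- n_reject + 1L
      h <- hstep * max(0.1, ctl$safety * ratio^(-1 / 4))
      if (h < ctl$h_min) {
        stop("adaptive step underflow at t = ", t, call. = FALSE)
      }
    }
  }
  new_trajectory(sys, times = times, h = hs,
                 states = do.call(cbind, states), mode = "adaptive",
                 n_accept = length(hs), n_reject = n_reject)
}

#' @export
print.iso_trajectory <- function(x, ...) {
  cat("<iso_trajectory> ", x$mode, "-step, ", length(x$times),
      " recorded times over [0, ", format(max(x$times)), "], ",
      x$n_accept, " accepted / ", x$n_reject, " rejected steps\n", sep = "")
  invisible(x)
}

#' Interpolate trajectory states at arbitrary times
#'
#' Cubic Hermite interpolation on each accepted step using the stored
#' states and right-hand-side slopes (locally O(h^4) accurate, exact at
#' the recorded times).
#'
#' @param traj an `iso_trajectory`.
#' @param times times within the integration span.
#' @return matrix (state dimension x length(times)).
#' @export
trajectory_states_at <- function(traj, times) {
  tt <- traj$times
  stopifnot(all(times >= tt[1] - 1e-12), all(times <= tt[length(tt)] + 1e-9))
  derivs <- new.env()
  get_f <- function(k) {
    key <- as.character(k)
    if (is.null(derivs[[key]])) {
      derivs[[key]] <- cascade_rhs(traj$sys, traj$states[, k], tt[k])
    }
    derivs[[key]]
  }
  out <- matrix(NA_real_, nrow(traj$states), length(times))
  for (i in seq_along(times)) {
    tau <- times[i]
    k <- findInterval(tau, tt, rightmost.closed = TRUE)
    k <- min(max(k, 1L), length(tt) - 1L)
    if (abs(tau - tt[k]) < 1e-14) {
      out[, i] <- traj$states[, k]
      next
    }
    if (abs(tau - tt[k + 1]) < 1e-14) {
      out[, i] <- traj$states[, k + 1]
      next
    }
    h <- tt[k + 1] - tt[k]
    th <- (tau - tt[k]) / h
    h00 <- 2 * th^3 - 3 * th^2 + 1
    h10 <- th^3 - 2 * th^2 + th
    h01 <- -2 * th^3 + 3 * th^2
    h11 <- th^3 - th^2
    out[, i] <- h00 * traj$states[, k] + h * h10 * get_f(k) +
      h01 * traj$states[, k + 1] + h * h11 * get_f(k + 1)
  }
  out
}
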
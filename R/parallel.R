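# Dependency-cascade parallel contract.
#
# Each SCC block's stage-k update may begin only after the same-stage
# values of the blocks it reads from (its parents in the condensation,
# plus convolution sources) have been delivered.  The scheduler here is a
# deterministic simulation of that contract: per-(block, stage) tasks are
# assigned round-robin to worker queues and executed one ready task per
# worker per round, with a watchdog that aborts on a blocked cycle.  The
# reduction order inside every block is fixed, so the result is
# bit-for-bit identical to the serial integrator for any worker count.

rk4_tableau <- list(
  a = list(numeric(0), c(1 / 2), c(0, 1 / 2), c(0, 0, 1)),
  c = c(0, 1 / 2, 1 / 2, 1),
  b = c(1, 2, 2, 1) / 6
)

ck_full_tableau <- list(
  a = c(list(numeric(0)), ck_tableau$a),
  c = c(0, vapply(ck_tableau$a, sum, numeric(1))),
  b = ck_tableau$b5,
  db = ck_tableau$b4 - ck_tableau$b5
)

# coefs[1]*ks[[1]] + coefs[2]*ks[[2]] + ... over the given rows, skipping
# zero coefficients; the shared accumulation used by serial and parallel
# paths so their arithmetic is identical elementwise.
acc_stages <- function(coefs, ks, rows = NULL) {
  v <- NULL
  for (j in seq_along(coefs)) {
    if (coefs[j] == 0) next
    kj <- if (is.null(rows)) ks[[j]] else ks[[j]][rows]
    v <- if (is.null(v)) coefs[j] * kj else v + coefs[j] * kj
  }
  if (is.null(v)) {
    v <- if (is.null(rows)) numeric(length(ks[[1]])) else numeric(length(rows))
  }
  v
}

step_with_tableau <- function(sys, y, t, h, tab) {
  ns <- length(tab$a)
  ks <- vector("list", ns)
  for (s in seq_len(ns)) {
    ys <- if (s == 1) y else y + h * acc_stages(tab$a[[s]], ks)
    ks[[s]] <- cascade_rhs(sys, ys, t + tab$c[s] * h)
  }
  out <- y + h * acc_stages(tab$b, ks)
  if (!all(is.finite(out))) {
    stop("non-finite state at t = ", t, call. = FALSE)
  }
  err <- if (!is.null(tab$db)) h * acc_stages(tab$db, ks) else NULL
  list(state = out, err = err)
}

# One parallel step under the dependency-cascade contract.
parallel_step <- function(sys, y, t, h, tab, workers) {
  nb <- length(sys$blocks)
  ns <- length(tab$a)
  rows <- lapply(seq_len(nb), function(b) block_rows(sys, b))
  deps <- lapply(seq_len(nb), function(b) {
    sort(unique(c(sys$blocks[[b]]$deps, b)))
  })
  ntot <- length(y)
  ks <- lapply(seq_len(ns), function(s) rep(NA_real_, ntot))
  out <- rep(NA_real_, ntot)
  done <- matrix(FALSE, nb, ns + 1L)  # last column: final combine
  tasks <- list()
  for (w in seq_len(workers)) {
    mine <- which(((seq_len(nb) - 1L) %% workers) == (w - 1L))
    queue <- list()
    for (s in seq_len(ns + 1L)) {
      for (b in mine) queue[[length(queue) + 1L]] <- c(b, s)
    }
    tasks[[w]] <- queue
  }
  heads <- rep(1L, workers)
  n_pending <- nb * (ns + 1L)
  while (n_pending > 0L) {
    progressed <- FALSE
    for (w in seq_len(workers)) {
      if (heads[w] > length(tasks[[w]])) next
      task <- tasks[[w]][[heads[w]]]
      b <- task[1]; s <- task[2]
      need <- if (s <= ns) seq_len(s - 1L) else seq_len(ns)
      if (any(deps[[b]] < 1L | deps[[b]] > nb)) next  # unsatisfiable
      if (length(need) && !all(done[deps[[b]], need])) next
      r <- rows[[b]]
      if (s <= ns) {
        ys <- rep(NA_real_, ntot)
        dep_rows <- unlist(rows[deps[[b]]])
        ys[dep_rows] <- if (s == 1) y[dep_rows] else
          y[dep_rows] + h * acc_stages(tab$a[[s]], ks, dep_rows)
        ks[[s]][r] <- rhs_block_y(sys, b, ys)
      } else {
        out[r] <- y[r] + h * acc_stages(tab$b, ks, r)
      }
      done[b, s] <- TRUE
      heads[w] <- heads[w] + 1L
      n_pending <- n_pending - 1L
      progressed <- TRUE
    }
    if (!progressed) {
      blocked <- which(!done[, ns + 1L])[1]
      stop("parallel scheduler deadlock: block ", blocked,
           " waiting on undelivered parent values", call. = FALSE)
    }
  }
  if (!all(is.finite(out))) {
    stop("non-finite state at t = ", t, call. = FALSE)
  }
  err <- if (!is.null(tab$db)) h * acc_stages(tab$db, ks) else NULL
  list(state = out, err = err)
}

#' Integrate under the parallel dependency-cascade contract
#'
#' Produces a trajectory identical (bit for bit, by fixed per-block
#' reduction order) to the corresponding serial integrator for any
#' `workers >= 1`.  In adaptive mode the pilot step-size sequence is
#' computed once per step on the pilot subsystem and broadcast, so it is
#' independent of the worker count.
#'
#' @param sys a `cascade_system` (plain or augmented).
#' @param mode `"constant"` or `"adaptive"`.
#' @param workers number of scheduler workers (>= 1).
#' @param step,t_end,controller,y0 as in [integrate_constant()] /
#'   [integrate_adaptive()].
#' @return an `iso_trajectory` (with a `workers` field).
#' @export
run_parallel <- function(sys, mode = c("constant", "adaptive"), workers = 1L,
                         step = NULL, t_end = NULL, controller = NULL,
                         y0 = NULL) {
  mode <- match.arg(mode)
  workers <- as.integer(workers)
  stopifnot(workers >= 1L)
  t_end <- t_end %||% sys$model$settings$t_end
  y <- y0 %||% initial_state(sys)
  if (mode == "constant") {
    step <- step %||% sys$model$settings$step
    if (sys$rate_bound > 0 && step * sys$rate_bound > 2.5) {
      warning("step ", step, " exceeds the explicit stability bound ",
              signif(2.5 / sys$rate_bound, 3),
              " for the fastest SCC block; expect amplified round-off",
              call. = FALSE)
    }
    nfull <- floor(t_end / step + 1e-9)
    hs <- rep(step, nfull)
    if (t_end - nfull * step > 1e-12 * t_end) hs <- c(hs, t_end - nfull * step)
    states <- matrix(NA_real_, length(y), length(hs) + 1L)
    states[, 1] <- y
    t <- 0
    for (k in seq_along(hs)) {
      y <- parallel_step(sys, y, t, hs[k], rk4_tableau, workers)$state
      t <- t + hs[k]
      states[, k + 1L] <- y
    }
    traj <- new_trajectory(sys, c(0, cumsum(hs)), hs, states, "constant")
  } else {
    st <- sys$model$settings
    ctl <- controller %||% step_controller(tol_scaling = st$tol_scaling,
                                           tol_addition = st$tol_addition)
    ctl$h_init <- ctl$h_init %||% st$step
    ctl$h_max <- min(ctl$h_max, t_end / 10)
    if (sys$rate_bound > 0) ctl$h_max <- min(ctl$h_max, 2.5 / sys$rate_bound)
    pil <- pilot_nodes(base_system(sys))
    psys <- subsystem_prefix(sys, max(pil$blocks))
    pidx <- pil$node_idx
    t <- 0
    h <- min(ctl$h_init, ctl$h_max)
    times <- 0; hs <- numeric(0); states <- list(y); n_reject <- 0L
    while (t < t_end - 1e-12 * t_end) {
      hstep <- min(h, t_end - t)
      # pilot step computed once (worker 1) and broadcast
      yp <- y[seq_len(psys$nx)]
      trial <- cash_karp_step(psys, yp, t, hstep)
      tol <- ctl$tol_scaling * abs(trial$state[pidx]) + ctl$tol_addition
      ratio <- max(abs(trial$err[pidx]) / tol)
      if (ratio <= 1) {
        y <- parallel_step(sys, y, t, hstep, ck_full_tableau, workers)$state
        t <- t + hstep
        times <- c(times, t)
        hs <- c(hs, hstep)
        states[[length(states) + 1L]] <- y
        grow <- if (ratio > 0) ctl$safety * ratio^(-1 / 5) else 5
        h <- min(hstep * min(5, grow), ctl$h_max)
      } else {
        n_reject <- n_reject + 1L
        h <- hstep * max(0.1, ctl$safety * ratio^(-1 / 4))
        if (h < ctl$h_min) stop("adaptive step underflow", call. = FALSE)
      }
    }
    traj <- new_trajectory(sys, times, hs, do.call(cbind, states),
                           "adaptive", length(hs), n_reject)
  }
  traj$workers <- workers
  traj
}
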
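# Tidy / glance / autoplot methods for trajectories.

#' Tidy a labeling trajectory into long format
#'
#' @param x an `iso_trajectory`.
#' @param sensitivities if `TRUE` return the sensitivity blocks (long
#'   over parameter) instead of the base MIDs.
#' @param ... unused.
#' @return tibble (time, metabolite, emu, weight, value) or, with
#'   sensitivities, (time, metabolite, emu, weight, parameter, value).
#' @method tidy iso_trajectory
#' @export
tidy.iso_trajectory <- function(x, sensitivities = FALSE, ...) {
  sys <- x$sys
  nt <- sys$node_tab
  if (!sensitivities) {
    base <- x$states[seq_len(sys$nx), , drop = FALSE]
    out <- tibble(
      time = rep(x$times, each = sys$nx),
      metabolite = rep(nt$metabolite, length(x$times)),
      emu = rep(nt$emu_key, length(x$times)),
      weight = rep(nt$weight, length(x$times)),
      value = as.vector(base)
    )
    return(out)
  }
  if (!inherits(sys, "augmented_cascade")) {
    stop("trajectory carries no sensitivities", call. = FALSE)
  }
  pieces <- lapply(seq_len(sys$npar), function(r) {
    S <- x$states[r * sys$nx + seq_len(sys$nx), , drop = FALSE]
    tibble(
      time = rep(x$times, each = sys$nx),
      metabolite = rep(nt$metabolite, length(x$times)),
      emu = rep(nt$emu_key, length(x$times)),
      weight = rep(nt$weight, length(x$times)),
      parameter = sys$par_names[r],
      value = as.vector(S)
    )
  })
  dplyr::bind_rows(pieces)
}

#' One-row trajectory summary
#'
#' @param x an `iso_trajectory`.
#' @param ... unused.
#' @method glance iso_trajectory
#' @export
glance.iso_trajectory <- function(x, ...) {
  cons <- conservation_report(x)
  tibble(
    mode = x$mode,
    t_end = max(x$times),
    n_accepted = x$n_accept,
    n_rejected = x$n_reject,
    n_states = nrow(x$states),
    max_mid_deviation = max(cons$mid$max_deviation, na.rm = TRUE),
    max_sens_deviation = if (nrow(cons$sensitivity))
      max(cons$sensitivity$max_deviation) else NA_real_
  )
}

#' Plot the labeling curves of a trajectory
#'
#' One panel per EMU, one curve per mass isotopomer weight.
#'
#' @param object an `iso_trajectory`.
#' @param emus optional character vector of EMU keys to show.
#' @param ... unused.
#' @method autoplot iso_trajectory
#' @export
autoplot.iso_trajectory <- function(object, emus = NULL, ...) {
  df <- tidy(object)
  if (!is.null(emus)) df <- df[df$emu %in% emus, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$value,
                                   colour = factor(.data$weight))) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~emu) +
    ggplot2::labs(x = "time (s)", y = "mass isotopomer fraction",
                  colour = "weight") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
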
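# ggplot2 displays for the result objects.

#' Plot an avalanche-shape profile
#'
#' Area-normalised shape with a standard-error ribbon where available, and
#' the extinction-rate perturbation `-A sin(nu * tau * T)` overlaid (scaled)
#' when the conditioning `T` is numeric and `params` are supplied.
#'
#' @param object A `bp_shape`.
#' @param params Optional [bp_params()] for the perturbation overlay.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bp_shape <- function(object, params = NULL, ...) {
  gg <- ggplot2::ggplot(object, ggplot2::aes(x = .data$tau, y = .data$value))
  if (!all(is.na(object$se))) {
    gg <- gg + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$value - 2 * .data$se,
                   ymax = .data$value + 2 * .data$se),
      fill = "grey80")
  }
  gg <- gg + ggplot2::geom_line(colour = "#4040a0")
  T_lab <- attr(object, "T")
  if (!is.null(params) && is.numeric(T_lab)) {
    pert <- -params$A * sin(params$nu * object$tau * T_lab)
    scale <- max(object$value) / max(abs(pert), 1e-12) / 4
    gg <- gg + ggplot2::geom_line(
      data = tibble::tibble(tau = object$tau, value = pert * scale),
      colour = "darkgreen", linetype = 2)
  }
  gg + ggplot2::labs(
    x = expression(tau == t / T), y = expression(V[1](tau)),
    title = if (is.numeric(T_lab)) sprintf("Avalanche shape, sT = %g", T_lab)
    else "Duration-averaged avalanche shape")
}

#' Plot ensemble moment estimates against the analytic predictions
#'
#' First and second moments with 3-standard-error bars, overlaid with the
#' exact closed forms ([first_moment()], [second_moment_exact()]).
#'
#' @param object A `bp_ensemble` run with a `grid`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bp_ensemble <- function(object, ...) {
  if (is.null(object$moments)) {
    stop("ensemble was run without a time grid; nothing to plot")
  }
  mom <- object$moments
  params <- object$params
  analytic <- tibble::tibble(
    st = rep(mom$st, 2),
    value = c(first_moment(params, mom$time),
              vapply(mom$time, function(t)
                as.numeric(second_moment_exact(params, t)), numeric(1))),
    moment = rep(c("E[N]", "E[N²]"), each = nrow(mom)))
  est <- tibble::tibble(
    st = rep(mom$st, 2),
    value = c(mom$mean_n, mom$mean_n2),
    se = c(mom$se_n, mom$se_n2),
    moment = rep(c("E[N]", "E[N²]"), each = nrow(mom)))
  ggplot2::ggplot(est, ggplot2::aes(x = .data$st, y = .data$value)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$value - 3 * .data$se,
                   ymax = .data$value + 3 * .data$se),
      size = 0.2) +
    ggplot2::geom_line(data = analytic, colour = "#4040a0") +
    ggplot2::facet_wrap(~moment, scales = "free_y") +
    ggplot2::labs(x = "st", y = NULL,
                  title = sprintf("Ensemble vs analytic moments (%d runs)",
                                  object$n_runs))
}

#' Plot a power-law fit
#'
#' Log-binned density histogram with the fitted truncated power law.
#'
#' @param object A `bp_powerlaw_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.bp_powerlaw_fit <- function(object, ...) {
  h <- object$histogram
  h <- h[h$count > 0, ]
  mid <- sqrt(h$bin_lo * h$bin_hi)
  a <- object$fit_range[1]; b <- object$fit_range[2]
  al <- object$exponent; cc <- object$offset %||% 0
  norm <- (al - 1) / ((a + cc)^(1 - al) - (b + cc)^(1 - al))
  fitline <- tibble::tibble(x = mid, y = norm * (mid + cc)^(-al))
  ggplot2::ggplot(tibble::tibble(x = mid, y = h$density),
                  ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = fitline, colour = "#a04040") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = if (object$kind == "duration") "sT" else "S",
      y = "density",
      title = sprintf("%s distribution: exponent %.3f", object$kind,
                      object$exponent))
}

#' Moment and survival curves for a parameter set
#'
#' Convenience line plots of the analytic observables on a grid, optionally
#' with the first-order approximations dashed.
#'
#' @param params A [bp_params()].
#' @param times Time grid.
#' @param first_order Overlay the first-order curves (dashed).
#' @return A ggplot.
#' @export
plot_moments <- function(params, times = seq(0, 30, length.out = 241),
                         first_order = TRUE) {
  df <- dplyr::bind_rows(
    moment_series(params, times, order = 1, method = "exact"),
    moment_series(params, times, order = 2, method = "exact"))
  gg <- ggplot2::ggplot(df, ggplot2::aes(x = .data$st, y = .data$value)) +
    ggplot2::geom_line(colour = "#4040a0") +
    ggplot2::facet_wrap(~order, scales = "free_y",
                        labeller = ggplot2::label_bquote(E[N^.(order)])) +
    ggplot2::labs(x = "st", y = NULL)
  if (first_order && abs(params$r) < 1e-12) {
    fo <- dplyr::bind_rows(
      moment_series(params, times, order = 1, method = "first_order"),
      moment_series(params, times, order = 2, method = "first_order"))
    gg <- gg + ggplot2::geom_line(data = fo, linetype = 2)
  }
  gg
}

#' @importFrom rlang .data
NULL
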
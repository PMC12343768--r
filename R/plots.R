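#' Plot methods
#'
#' `autoplot()` methods give quick diagnostic figures for the main result
#' types: survival curves (log-y step plot, optionally with a bi-exponential
#' fit overlaid), interaction maps (heat map, attractive = negative shown in
#' magenta-to-green divergence), grammar reports (feature-by-IDR z-score
#' tiles, masked at |z| < 1), and pooled recruitment curves (mean with SEM
#' ribbon).
#'
#' @param object The object to plot.
#' @param ... Unused.
#' @name condensatr-plots
NULL

#' @rdname condensatr-plots
#' @param fit Optional `biexp_fit` overlaid on the empirical curve.
#' @method autoplot survival_curve
#' @export
autoplot.survival_curve <- function(object, fit = NULL, ...) {
  p <- ggplot2::ggplot(object, ggplot2::aes(x = .data$time, y = .data$survival)) +
    ggplot2::geom_step() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "dwell time (s)", y = "1 - CDF")
  if (!is.null(fit)) {
    grid <- tibble(time = seq(0, max(object$time), length.out = 200))
    grid$survival <- fit$A * exp(-grid$time / fit$tau_ns) +
      (1 - fit$A) * exp(-grid$time / fit$tau_s)
    p <- p + ggplot2::geom_line(data = grid, colour = "red")
  }
  p
}

#' @rdname condensatr-plots
#' @method autoplot intermap
#' @export
autoplot.intermap <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$window_a, .data$window_b, fill = .data$epsilon)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "magenta", mid = "white", high = "darkgreen") +
    ggplot2::labs(
      x = sprintf("%s window start", object$id_a),
      y = sprintf("%s window start", object$id_b),
      fill = "epsilon"
    )
}

#' @rdname condensatr-plots
#' @method autoplot grammar_report
#' @export
autoplot.grammar_report <- function(object, ...) {
  df <- dplyr::mutate(object, z_shown = ifelse(.data$display, .data$z, NA_real_))
  ggplot2::ggplot(df, ggplot2::aes(.data$idr_id, .data$feature, fill = .data$z_shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "blue", mid = "white", high = "red", na.value = "grey95"
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "z")
}

#' @rdname condensatr-plots
#' @method autoplot recruitment_series
#' @export
autoplot.recruitment_series <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$t_min, .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem),
      alpha = 0.3
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "intensity (a.u.)")
}

#' Plot a sliding-window charge profile
#'
#' @param profile Tibble from [charge_profile()].
#' @return A ggplot object.
#' @export
plot_charge_profile <- function(profile) {
  ggplot2::ggplot(profile, ggplot2::aes(.data$position, .data$value)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "residue", y = "mean net charge per residue")
}
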
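#' Plot a fitted signal curve with the observations it was fit to
#'
#' Observations are drawn at their alternative-interval midpoints at
#' `log_rr` relative to the reference interval, sized by inverse variance;
#' trimmed observations are hollow.
#'
#' @param object A [fit_signal()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bop_signal_fit <- function(object, ...) {
  grid <- signal_grid(object)
  pts <- dplyr::mutate(
    object$data,
    midpoint = (.data$alt_lower + .data$alt_upper) / 2,
    kept = object$trim_mask
  )
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$exposure, y = .data$log_rr)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(
      data = pts,
      ggplot2::aes(
        x = .data$midpoint, y = .data$log_rr,
        size = 1 / .data$se_log_rr^2, shape = .data$kept
      ),
      alpha = 0.6
    ) +
    ggplot2::geom_line(linewidth = 1, colour = "#b2182b") +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1)) +
    ggplot2::guides(size = "none") +
    ggplot2::labs(
      x = "Exposure (g/day)", y = "log RR vs 0 g/day",
      shape = "Kept"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a risk curve with conventional and conservative uncertainty
#'
#' @param object A [predict_risk_curve()] result.
#' @param rr_scale Plot on the RR scale rather than log RR.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bop_risk_curve <- function(object, rr_scale = FALSE, ...) {
  df <- tibble::as_tibble(object)
  tr <- if (rr_scale) exp else identity
  ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = tr(.data$conservative_lo), ymax = tr(.data$conservative_hi)
      ),
      fill = "#fddbc7", alpha = 0.8
    ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = tr(.data$conventional_lo), ymax = tr(.data$conventional_hi)
      ),
      fill = "#ef8a62", alpha = 0.6
    ) +
    ggplot2::geom_hline(
      yintercept = tr(0), linetype = "dashed", colour = "grey60"
    ) +
    ggplot2::geom_line(
      ggplot2::aes(y = tr(.data$log_rr)), linewidth = 1, colour = "#b2182b"
    ) +
    ggplot2::labs(
      x = "Exposure (g/day)",
      y = if (rr_scale) "RR vs 0 g/day" else "log RR vs 0 g/day"
    ) +
    ggplot2::theme_minimal()
}

#' Modified funnel plot for small-study effects
#'
#' Residuals (relative to zero) against the residual standard deviation
#' that combines the reported SE with between-study heterogeneity, with the
#' pseudo-95% funnel.
#'
#' @param object A [egger_regression()] result (or a [residual_table()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bop_egger <- function(object, ...) {
  plot_funnel(if (inherits(object, "bop_egger")) object$data else object)
}

#' @rdname autoplot.bop_egger
#' @export
plot_funnel <- function(object) {
  df <- if (inherits(object, "bop_egger")) object$data else object
  sd_max <- max(df$residual_sd) * 1.05
  funnel <- tibble::tibble(
    residual_sd = c(0, sd_max), lo = -Z975 * c(0, sd_max),
    hi = Z975 * c(0, sd_max)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$residual, y = .data$residual_sd)) +
    ggplot2::geom_line(
      data = funnel, ggplot2::aes(x = .data$lo, y = .data$residual_sd),
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::geom_line(
      data = funnel, ggplot2::aes(x = .data$hi, y = .data$residual_sd),
      linetype = "dotted", colour = "grey50"
    ) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(
      x = "Residual (log RR)",
      y = "Residual s.d. (incl. heterogeneity)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a BPRF against the mean risk curve
#'
#' @param object A [compute_bprf()] result.
#' @param mean_beta Optional mean-curve coefficient to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.bop_bprf <- function(object, mean_beta = NULL, ...) {
  df <- object$grid
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$exposure)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line(
      ggplot2::aes(y = .data$log_bprf), linewidth = 1, colour = "#2166ac"
    ) +
    ggplot2::labs(x = "Exposure (g/day)", y = "log BPRF") +
    ggplot2::theme_minimal()
  if (!is.null(mean_beta)) {
    p <- p + ggplot2::geom_line(
      ggplot2::aes(y = mean_beta * .data$log_rr),
      linetype = "longdash", colour = "#b2182b"
    )
  }
  p
}
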
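#' Residuals and heterogeneity-inflated standard deviations
#'
#' Builds the data behind the modified funnel plot: per-observation
#' residuals relative to the fixed-effect prediction,
#' `r_i = y_i - (beta_hat + sum_j delta_j x_ij) * s_i`, and the residual
#' standard deviation `sqrt(sigma_i^2 + gamma*)` combining the reported SE
#' with between-study heterogeneity.
#'
#' @param table A study table; defaults to the signal fit's data.
#' @param fit A [fit_linear_mixed()] result.
#' @param signal_fit A [fit_signal()] result.
#' @param gamma_star Heterogeneity upper quantile (default from
#'   [gamma_upper_quantile()]).
#' @return A tibble with columns `study_id`, `residual`, `residual_sd`,
#'   `trimmed` (TRUE when the observation was excluded by signal trimming).
#' @export
residual_table <- function(table = NULL, fit, signal_fit = fit$signal_fit,
                           gamma_star = NULL) {
  table <- if (is.null(table)) signal_fit$data else as_study_table(table)
  gamma_star <- gamma_star %||% gamma_upper_quantile(fit)
  s <- predict_signal(signal_fit, table)
  pred <- fit$beta * s
  for (cv in fit$selected_covariates) {
    pred <- pred + fit$delta[[cv]] * table[[cv]] * s
  }
  trimmed <- if (nrow(table) == length(signal_fit$trim_mask)) {
    !signal_fit$trim_mask
  } else {
    rep(FALSE, nrow(table))
  }
  tibble::tibble(
    study_id = as.character(table$study_id),
    residual = table$log_rr - pred,
    residual_sd = sqrt(table$se_log_rr^2 + gamma_star),
    trimmed = trimmed
  )
}

#' Egger's regression for small-study effects
#'
#' Regresses model residuals on their heterogeneity-inflated standard
#' deviations by weighted least squares (weights `1 / residual_sd^2`) and
#' tests the slope with a two-sided t-test. A significant slope indicates
#' that imprecise observations systematically deviate from the model -- the
#' signature of publication or reporting bias. Observations trimmed during
#' curve fitting are excluded by default.
#'
#' @param residuals A [residual_table()] result.
#' @param alpha Flagging level (default 0.05).
#' @param include_trimmed Keep trimmed observations in the regression.
#' @return An object of class `bop_egger` with `slope`, `intercept`,
#'   `se_slope`, `p_value`, `flagged`, `n`, and the analysed `data`.
#' @export
egger_regression <- function(residuals, alpha = 0.05,
                             include_trimmed = FALSE) {
  if (!all(c("residual", "residual_sd") %in% names(residuals))) {
    abort("`residuals` must come from `residual_table()`.")
  }
  dat <- residuals
  if (!include_trimmed && "trimmed" %in% names(dat)) {
    dat <- dat[!dat$trimmed, , drop = FALSE]
  }
  if (nrow(dat) < 3) abort("Egger's regression needs at least 3 observations.")
  if (length(unique(dat$residual_sd)) < 2) {
    abort("Residual standard deviations are constant; slope undefined.")
  }
  m <- lm(residual ~ residual_sd, data = dat, weights = 1 / dat$residual_sd^2)
  sm <- suppressWarnings(summary(m))$coefficients
  slope <- sm["residual_sd", "Estimate"]
  p_value <- sm["residual_sd", "Pr(>|t|)"]
  # a numerically perfect fit yields a 0/0 t-statistic; resolve by the slope
  if (!is.finite(p_value)) p_value <- if (abs(slope) < 1e-12) 1 else 0
  structure(
    list(
      slope = slope,
      intercept = sm["(Intercept)", "Estimate"],
      se_slope = sm["residual_sd", "Std. Error"],
      p_value = p_value,
      flagged = p_value < alpha,
      alpha = alpha, n = nrow(dat), data = dat
    ),
    class = "bop_egger"
  )
}

#' @export
print.bop_egger <- function(x, ...) {
  cat("Egger's regression for small-study effects\n")
  cat(sprintf(
    "  slope = %.4f (SE %.4f), p = %.4g, %s at alpha = %.2f (n = %d)\n",
    x$slope, x$se_slope, x$p_value,
    if (x$flagged) "FLAGGED" else "not flagged", x$alpha, x$n
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bop_egger <- function(x, ...) {
  tibble::tibble(
    term = c("intercept", "slope"),
    estimate = c(x$intercept, x$slope),
    std.error = c(NA_real_, x$se_slope),
    p.value = c(NA_real_, x$p_value)
  )
}

#' @exportS3Method generics::glance
glance.bop_egger <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, p.value = x$p_value,
    flagged = x$flagged, n = x$n
  )
}
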
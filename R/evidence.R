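#' Burden-of-proof risk function (BPRF)
#'
#' The BPRF is the 95th (protective) or 5th (harmful) quantile log-RR curve
#' closest to the null, once between-study heterogeneity is carried in the
#' uncertainty: the weakest association consistent with the data. Under the
#' signal-scaling model the quantile acts on the coefficient,
#' `beta_cons = beta_hat - z_level * sqrt(se_beta^2 + gamma*)`, and
#' `log-BPRF(x) = beta_cons * f(x)`. Because the protective signal satisfies
#' `f <= 0` with `beta_hat > 0`, the downward shift of the coefficient always
#' moves the curve toward the null; if `beta_cons < 0` the BPRF lies on the
#' opposite side of the null and the risk-outcome score will be negative.
#'
#' @param fit A [fit_linear_mixed()] result.
#' @param signal_fit A [fit_signal()] result.
#' @param gamma_star Heterogeneity upper quantile from
#'   [gamma_upper_quantile()].
#' @param direction `"protective"` or `"harmful"`.
#' @param level One-sided quantile level (default 0.95).
#' @return An object of class `bop_bprf`: `beta_cons`, `direction`, the
#'   signal curve, and a grid of log-BPRF values.
#' @export
compute_bprf <- function(fit, signal_fit = fit$signal_fit, gamma_star,
                         direction = c("protective", "harmful"),
                         level = 0.95) {
  direction <- match.arg(direction)
  if (missing(gamma_star) || is.null(gamma_star)) {
    abort("`gamma_star` is required; compute it with `gamma_upper_quantile()`.")
  }
  curve <- .as_curve(signal_fit)
  beta_cons <- fit$beta - qnorm(level) * sqrt(fit$se_beta^2 + gamma_star)
  grid <- signal_grid(signal_fit)
  structure(
    list(
      beta_cons = beta_cons, direction = direction, level = level,
      gamma_star = gamma_star, curve = curve,
      grid = dplyr::mutate(grid, log_bprf = beta_cons * .data$log_rr)
    ),
    class = "bop_bprf"
  )
}

#' Exposure distribution percentiles of a study table
#'
#' Percentiles of the pooled alternative-interval midpoints, one weight per
#' observation, using the linear-interpolation convention (rank
#' `p * (n - 1) + 1`).
#'
#' @param table A study table.
#' @param p_lo,p_hi Percentiles (default 15 and 85).
#' @return Named numeric vector `c(p_lo, p_hi)` in g/day.
#' @export
exposure_percentiles <- function(table, p_lo = 15, p_hi = 85) {
  table <- as_study_table(table)
  mids <- (table$alt_lower + table$alt_upper) / 2
  q <- quantile(mids, c(p_lo, p_hi) / 100, type = 7)
  setNames(as.numeric(q), c(paste0("p", p_lo), paste0("p", p_hi)))
}

#' Risk-outcome score (ROS)
#'
#' The signed mean of the log-BPRF over the observed exposure range
#' `[p15, p85]`: `ros = sign * (1 / (p85 - p15)) * integral log-BPRF(x) dx`
#' with sign -1 for protective and +1 for harmful risks, so that a higher
#' positive score always indicates stronger evidence and a negative score
#' indicates that the conservative interpretation does not reject the null.
#' The average is the exact integral mean over the interval (piecewise
#' polynomial for spline-based BPRFs, quadrature for function inputs).
#'
#' @param bprf A [compute_bprf()] result, a function of exposure returning
#'   log-BPRF values, or a single constant log-BPRF value.
#' @param p15,p85 Averaging range in g/day (`p15 <= p85`; equal values give
#'   a point evaluation).
#' @param direction `"protective"` or `"harmful"`; defaults to the
#'   direction recorded in `bprf` when available.
#' @return The scalar ROS.
#' @export
compute_ros <- function(bprf, p15 = 0, p85 = 1,
                        direction = c("protective", "harmful")) {
  if (inherits(bprf, "bop_bprf") && missing(direction)) {
    direction <- bprf$direction
  }
  direction <- match.arg(direction)
  if (!is.numeric(p15) || !is.numeric(p85) || p15 > p85) {
    abort("Need p15 <= p85.")
  }
  sgn <- if (direction == "protective") -1 else 1
  mean_bprf <-
    if (inherits(bprf, "bop_bprf")) {
      bprf$beta_cons * interval_average(bprf$curve, c(p15, p85))
    } else if (is.function(bprf)) {
      if (p15 == p85) {
        bprf(p15)
      } else {
        integrate(bprf, p15, p85, rel.tol = 1e-10)$value / (p85 - p15)
      }
    } else if (is.numeric(bprf) && length(bprf) == 1) {
      bprf
    } else {
      abort("`bprf` must be a `bop_bprf`, a function, or a constant.")
    }
  sgn * mean_bprf
}

#' Star rating from a risk-outcome score
#'
#' Maps the ROS to a one-to-five star rating through the published
#' percent-change cut points. For protective risks the implied average
#' decrease in risk is `d = 1 - exp(-ros)` with ranges 0-13% (two stars),
#' >13-34% (three), >34-46% (four), >46% (five); for harmful risks the
#' implied increase is `h = exp(ros) - 1` with ranges 0-15%, >15-50%,
#' >50-85%, >85%. A non-positive ROS is one star: the association does not
#' achieve significance under the conservative interpretation.
#'
#' @param ros Risk-outcome score.
#' @param direction `"protective"` or `"harmful"`.
#' @return Integer star rating, 1-5.
#' @export
star_rating <- function(ros, direction = c("protective", "harmful")) {
  direction <- match.arg(direction)
  if (!is.finite(ros)) abort("`ros` must be finite.")
  if (ros <= 0) return(1L)
  if (direction == "protective") {
    d <- 1 - exp(-ros)
    cuts <- c(0.13, 0.34, 0.46)
  } else {
    d <- exp(ros) - 1
    cuts <- c(0.15, 0.50, 0.85)
  }
  as.integer(2L + findInterval(d, cuts, left.open = TRUE))
}

#' Theoretical minimum risk exposure level (TMREL)
#'
#' For a protective exposure the TMREL corresponds to high real-world
#' consumption supported by the data: each study contributes its single
#' highest-consumption category; the TMREL lower bound is the 85th
#' percentile of those categories' lower limits across studies, and the
#' upper bound is the 85th percentile of their midpoints (same
#' linear-interpolation percentile convention as
#' [exposure_percentiles()]). Pass a list of study tables to pool across
#' outcomes.
#'
#' @param tables A study table, or a list of study tables to pool.
#' @param pct Percentile (default 85).
#' @return A one-row tibble with `lower` and `upper` (g/day).
#' @export
compute_tmrel <- function(tables, pct = 85) {
  if (is.data.frame(tables)) tables <- list(tables)
  tops <- purrr::map_dfr(tables, function(tb) {
    tb <- as_study_table(tb)
    dplyr::summarise(
      dplyr::group_by(tb, .data$study_id),
      lower = .data$alt_lower[which.max((.data$alt_lower + .data$alt_upper) / 2)],
      upper = .data$alt_upper[which.max((.data$alt_lower + .data$alt_upper) / 2)],
      .groups = "drop"
    )
  })
  if (!nrow(tops)) abort("No studies supplied.")
  mids <- (tops$lower + tops$upper) / 2
  tibble::tibble(
    lower = as.numeric(quantile(tops$lower, pct / 100, type = 7)),
    upper = as.numeric(quantile(mids, pct / 100, type = 7))
  )
}

#' Evidence score for a fitted risk-outcome pair
#'
#' Bundles the conservative coefficient, BPRF, exposure percentiles, ROS,
#' and star rating into one object.
#'
#' @param fit A [fit_linear_mixed()] result.
#' @param signal_fit A [fit_signal()] result.
#' @param table The study table (defaults to the signal fit's data).
#' @param direction `"protective"` or `"harmful"`; defaults to the sign of
#'   the fitted mean curve.
#' @param het_level Quantile level for [gamma_upper_quantile()].
#' @param level One-sided BPRF quantile level.
#' @return An object of class `bop_evidence_score`.
#' @export
evidence_score <- function(fit, signal_fit = fit$signal_fit, table = NULL,
                           direction = NULL, het_level = 0.95, level = 0.95) {
  table <- if (is.null(table)) signal_fit$data else as_study_table(table)
  gamma_star <- gamma_upper_quantile(fit, level = het_level)
  if (is.null(direction)) {
    mean_tail <- fit$beta * .curve_eval(
      .as_curve(signal_fit),
      max(.as_curve(signal_fit)$breaks)
    )
    direction <- if (mean_tail <= 0) "protective" else "harmful"
  }
  bprf <- compute_bprf(fit, signal_fit, gamma_star, direction, level = level)
  pc <- exposure_percentiles(table)
  ros <- compute_ros(bprf, pc[[1]], pc[[2]], direction)
  structure(
    list(
      gamma_star = gamma_star, beta_conservative = bprf$beta_cons,
      bprf = bprf, p15 = pc[[1]], p85 = pc[[2]],
      ros = ros, stars = star_rating(ros, direction),
      direction = direction
    ),
    class = "bop_evidence_score"
  )
}

# reporting convention: two decimals for |ros| >= 0.01, else three
.format_ros <- function(ros) {
  digits <- if (abs(ros) >= 0.01) 2 else 3
  formatC(round(ros, digits), format = "f", digits = digits)
}

#' @export
print.bop_evidence_score <- function(x, ...) {
  cat("Burden-of-proof evidence score\n")
  cat(sprintf(
    "  direction %s, ROS = %s, %d star%s\n",
    x$direction, .format_ros(x$ros), x$stars, if (x$stars > 1) "s" else ""
  ))
  cat(sprintf(
    "  beta_cons = %.4f, gamma* = %.5f, averaged over [%.1f, %.1f] g/day\n",
    x$beta_conservative, x$gamma_star, x$p15, x$p85
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bop_evidence_score <- function(x, ...) {
  tibble::tibble(
    term = c("ros", "stars", "beta_conservative", "gamma_star", "p15", "p85"),
    estimate = c(
      x$ros, x$stars, x$beta_conservative, x$gamma_star, x$p15, x$p85
    )
  )
}

#' @exportS3Method generics::glance
glance.bop_evidence_score <- function(x, ...) {
  tibble::tibble(
    ros = x$ros, stars = x$stars, direction = x$direction,
    beta_conservative = x$beta_conservative, gamma_star = x$gamma_star,
    p15 = x$p15, p85 = x$p85
  )
}
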
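#' Linear mixed-effects meta-regression on the fitted signal
#'
#' Scales the non-linear signal through the model
#' `y_i = (beta + u_s) * s_i + sum_j delta_j x_ij * s_i + eps_i` with
#' `u_s ~ N(0, gamma)` (a multiplicative random slope per study) and
#' `eps_i ~ N(0, sigma_i^2)` with known observation variances. `beta` is the
#' overall scaling of the signal (approximately 1 when the signal curve
#' already matches the data), the `delta_j` are study-design bias-covariate
#' effects acting multiplicatively on the signal, and `gamma` is the
#' remaining unexplained between-study heterogeneity, estimated by profile
#' maximum likelihood over `gamma >= 0`. The standard error of `gamma` comes
#' from the Fisher information of the heterogeneity parameter, which stays
#' positive even when `gamma_hat` is zero, driving the sparse-data
#' correction in [gamma_upper_quantile()].
#'
#' Observations trimmed during signal fitting are excluded from the
#' meta-regression.
#'
#' @param table A study table; defaults to the table the signal was fit to.
#' @param signal_fit A [fit_signal()] result.
#' @param covariates Character vector of `cv_*` columns to adjust for.
#' @return An object of class `bop_mixed_fit` with elements `beta`,
#'   `se_beta`, `delta`, `se_delta`, `gamma_hat`, `se_gamma`,
#'   `selected_covariates`, `vcov_fixed`, `logLik`, `n_obs`, `n_studies`,
#'   and the per-observation frame `model_frame`.
#' @export
fit_linear_mixed <- function(table = NULL, signal_fit, covariates = character()) {
  if (!inherits(signal_fit, "bop_signal_fit")) {
    abort("`signal_fit` must be a `bop_signal_fit`.")
  }
  table <- if (is.null(table)) signal_fit$data else as_study_table(table)
  same_data <- nrow(table) == length(signal_fit$trim_mask)
  keep <- if (same_data) signal_fit$trim_mask else rep(TRUE, nrow(table))
  tab <- table[keep, , drop = FALSE]
  s <- predict_signal(signal_fit, tab)
  if (max(abs(s)) == 0) abort("Signals are all zero; beta is unidentified.")
  y <- tab$log_rr
  sigma <- tab$se_log_rr
  study <- as.character(tab$study_id)
  n_studies <- length(unique(study))

  missing_cv <- setdiff(covariates, names(tab))
  if (length(missing_cv)) {
    abort(paste0(
      "Covariate column(s) not in table: ",
      paste(missing_cv, collapse = ", "), "."
    ))
  }
  # fixed-effect design: signal plus covariate-by-signal interactions
  Fd <- cbind(signal = s)
  for (cv in covariates) Fd <- cbind(Fd, tab[[cv]] * s)
  colnames(Fd) <- c("signal", covariates)
  if (qr(Fd)$rank < ncol(Fd)) {
    abort("Rank-deficient design: collinear bias covariates.")
  }

  blocks <- split(seq_along(y), study)
  w <- 1 / sigma^2

  profile <- function(gamma) .mixed_gls(Fd, y, w, blocks, gamma)

  if (n_studies < 2) {
    gamma_hat <- 0
    se_gamma <- NA_real_
    gamma_estimable <- FALSE
  } else {
    gamma_estimable <- TRUE
    # crude per-study slope spread to bound the profile search
    b_s <- vapply(blocks, function(ix) {
      sum(w[ix] * y[ix] * s[ix]) / max(sum(w[ix] * s[ix]^2), 1e-12)
    }, numeric(1))
    upper <- max(1, 4 * stats::var(b_s), na.rm = TRUE)
    opt <- optimize(function(g) profile(g)$loglik,
      interval = c(0, upper), maximum = TRUE, tol = 1e-9
    )
    gamma_hat <- if (profile(0)$loglik >= opt$objective) 0 else opt$maximum
    info <- .gamma_fisher_info(s, w, blocks, gamma_hat)
    se_gamma <- 1 / sqrt(info)
  }

  sol <- profile(gamma_hat)
  est <- drop(sol$beta)
  se <- sqrt(diag(sol$vcov))
  structure(
    list(
      beta = est[["signal"]], se_beta = se[["signal"]],
      delta = est[setdiff(names(est), "signal")],
      se_delta = se[setdiff(names(est), "signal")],
      gamma_hat = gamma_hat, se_gamma = se_gamma,
      gamma_estimable = gamma_estimable,
      selected_covariates = covariates,
      vcov_fixed = sol$vcov, logLik = sol$loglik,
      n_obs = length(y), n_studies = n_studies,
      model_frame = tibble::tibble(
        study_id = study, y = y, sigma = sigma, signal = s
      ),
      signal_fit = signal_fit
    ),
    class = "bop_mixed_fit"
  )
}

# GLS and profile log-likelihood at fixed gamma, using the Woodbury identity
# per study block: V_s^{-1} = W - k (W z)(W z)' with k = gamma/(1 + gamma c_s)
.mixed_gls <- function(Fd, y, w, blocks, gamma) {
  p <- ncol(Fd)
  XtVX <- matrix(0, p, p)
  XtVy <- numeric(p)
  ytVy <- 0
  logdet <- 0
  for (ix in blocks) {
    Fs <- Fd[ix, , drop = FALSE]
    ys <- y[ix]
    ws <- w[ix]
    zs <- Fs[, 1] # the signal column is the random-slope loading
    c_s <- sum(ws * zs^2)
    k <- gamma / (1 + gamma * c_s)
    a <- crossprod(Fs, ws * zs)
    b <- sum(ws * zs * ys)
    XtVX <- XtVX + crossprod(Fs, Fs * ws) - k * tcrossprod(a)
    XtVy <- XtVy + crossprod(Fs, ws * ys) - k * a * b
    ytVy <- ytVy + sum(ws * ys^2) - k * b^2
    logdet <- logdet + sum(log(1 / ws)) + log1p(gamma * c_s)
  }
  beta <- solve(XtVX, XtVy)
  quad <- ytVy - sum(beta * XtVy)
  loglik <- -0.5 * (length(y) * log(2 * pi) + logdet + quad)
  list(
    beta = setNames(drop(beta), colnames(Fd)),
    vcov = solve(XtVX), loglik = loglik
  )
}

# Fisher information for the heterogeneity parameter:
# I(gamma) = 1/2 sum_s (z_s' V_s^-1 z_s)^2, z_s the signal loadings
.gamma_fisher_info <- function(s, w, blocks, gamma) {
  0.5 * sum(vapply(blocks, function(ix) {
    c_s <- sum(w[ix] * s[ix]^2)
    (c_s / (1 + gamma * c_s))^2
  }, numeric(1)))
}

#' Fisher-information upper quantile of between-study heterogeneity
#'
#' Returns `gamma* = gamma_hat + z_level * se_gamma` (floored at zero), the
#' upper quantile of the heterogeneity parameter's sampling distribution.
#' With few studies `gamma_hat` may be zero purely from lack of data; the
#' Fisher-information standard error keeps `gamma*` positive in such
#' data-sparse situations, guarding against underestimated heterogeneity.
#'
#' @param fit A [fit_linear_mixed()] result.
#' @param level Quantile level (default 0.95).
#' @return The scalar `gamma*`.
#' @export
gamma_upper_quantile <- function(fit, level = 0.95) {
  if (!inherits(fit, "bop_mixed_fit")) abort("`fit` must be a `bop_mixed_fit`.")
  if (is.null(fit$se_gamma) || is.na(fit$se_gamma)) {
    abort("`se_gamma` is unavailable (single-study fit); gamma* undefined.")
  }
  max(0, fit$gamma_hat + qnorm(level) * fit$se_gamma)
}

#' Select study-design bias covariates
#'
#' Each candidate is first tested singly: it passes the screen when the
#' z-statistic of its effect reaches the two-sided `alpha` critical value.
#' Survivors are refit jointly and any covariate losing significance in the
#' joint model is dropped in a single backward pass.
#'
#' @param table A study table; defaults to the signal fit's table.
#' @param signal_fit A [fit_signal()] result.
#' @param candidates Candidate `cv_*` column names; defaults to all present.
#' @param alpha Significance level (default 0.05).
#' @return Character vector of selected covariate names (possibly empty).
#' @export
select_bias_covariates <- function(table = NULL, signal_fit,
                                   candidates = NULL, alpha = 0.05) {
  tab <- if (is.null(table)) signal_fit$data else as_study_table(table)
  candidates <- candidates %||% covariate_names(tab)
  if (!length(candidates)) return(character(0))
  crit <- qnorm(1 - alpha / 2)

  usable <- character(0)
  for (cv in candidates) {
    if (!cv %in% names(tab)) {
      abort(paste0("Candidate covariate `", cv, "` not found in table."))
    }
    if (length(unique(tab[[cv]])) < 2) {
      warn(paste0("Covariate `", cv, "` is constant; skipped."))
      next
    }
    usable <- c(usable, cv)
  }

  zstat <- function(fit, cv) abs(fit$delta[[cv]] / fit$se_delta[[cv]])
  screened <- usable[vapply(usable, function(cv) {
    fit <- fit_linear_mixed(tab, signal_fit, covariates = cv)
    zstat(fit, cv) >= crit
  }, logical(1))]
  if (length(screened) <= 1) return(screened)

  joint <- fit_linear_mixed(tab, signal_fit, covariates = screened)
  screened[vapply(screened, function(cv) zstat(joint, cv) >= crit, logical(1))]
}

#' Mean risk curve with conventional and conservative uncertainty
#'
#' Predicts the log-RR curve at the reference covariate level (all bias
#' covariates at their least-biased level, coded 0):
#' `mean(x) = beta_hat * f(x)`. The conventional 95% UI scales the curve by
#' `beta_hat +/- z * se_beta`; the conservative UI additionally carries
#' between-study heterogeneity, replacing `se_beta` with
#' `sqrt(se_beta^2 + gamma*)`, so it contains the conventional interval
#' pointwise.
#'
#' @param fit A [fit_linear_mixed()] result.
#' @param signal_fit A [fit_signal()] result.
#' @param grid Exposure grid (g/day); defaults to 101 points over the
#'   curve domain.
#' @param level UI level (default 0.95).
#' @param gamma_star Heterogeneity upper quantile; defaults to
#'   [gamma_upper_quantile()] at its default level.
#' @return A tibble of class `bop_risk_curve` with columns `exposure`,
#'   `log_rr`, `rr`, `conventional_lo`, `conventional_hi`,
#'   `conservative_lo`, `conservative_hi` (log-RR scale bounds).
#' @export
predict_risk_curve <- function(fit, signal_fit = fit$signal_fit, grid = NULL,
                               level = 0.95, gamma_star = NULL) {
  curve <- .as_curve(signal_fit)
  dom <- range(curve$breaks)
  grid <- grid %||% seq(dom[1], dom[2], length.out = 101)
  if (any(grid < dom[1] - 1e-9 | grid > dom[2] + 1e-9)) {
    abort("Prediction grid extends outside the curve domain.")
  }
  gamma_star <- gamma_star %||% gamma_upper_quantile(fit)
  z <- qnorm(1 - (1 - level) / 2)
  f <- .curve_eval(curve, grid)
  se_cons <- sqrt(fit$se_beta^2 + gamma_star)
  bounds <- function(se) {
    lo <- (fit$beta - z * se) * f
    hi <- (fit$beta + z * se) * f
    list(lo = pmin(lo, hi), hi = pmax(lo, hi))
  }
  conv <- bounds(fit$se_beta)
  cons <- bounds(se_cons)
  out <- tibble::tibble(
    exposure = grid,
    log_rr = fit$beta * f,
    rr = exp(fit$beta * f),
    conventional_lo = conv$lo, conventional_hi = conv$hi,
    conservative_lo = cons$lo, conservative_hi = cons$hi
  )
  structure(out,
    class = c("bop_risk_curve", class(out)),
    beta = fit$beta, se_beta = fit$se_beta,
    gamma_star = gamma_star, level = level, curve = curve
  )
}

#' Percent change in risk between two exposures
#'
#' Reports `100 * (1 - exp(mean_log_rr(x_to) - mean_log_rr(x_from)))`, the
#' percent lower risk at `x_to` relative to `x_from`, and applies the same
#' transform to the conventional and conservative UI bounds.
#'
#' @param curve A [predict_risk_curve()] result.
#' @param x_from,x_to Exposures in g/day within the curve domain.
#' @return A one-row tibble with `mean`, `conventional_lo/hi`, and
#'   `conservative_lo/hi` percent reductions.
#' @export
percent_change <- function(curve, x_from, x_to) {
  if (!inherits(curve, "bop_risk_curve")) {
    abort("`curve` must be a `bop_risk_curve`.")
  }
  spline <- attr(curve, "curve")
  beta <- attr(curve, "beta")
  se_beta <- attr(curve, "se_beta")
  gamma_star <- attr(curve, "gamma_star")
  z <- qnorm(1 - (1 - attr(curve, "level")) / 2)
  df <- .curve_eval(spline, x_to) - .curve_eval(spline, x_from)
  pct <- function(b) 100 * (1 - exp(b * df))
  band <- function(se) sort(pct(c(beta - z * se, beta + z * se)))
  conv <- band(se_beta)
  cons <- band(sqrt(se_beta^2 + gamma_star))
  tibble::tibble(
    mean = pct(beta),
    conventional_lo = conv[1], conventional_hi = conv[2],
    conservative_lo = cons[1], conservative_hi = cons[2]
  )
}

#' @export
print.bop_mixed_fit <- function(x, ...) {
  cat("Mixed-effects signal meta-regression\n")
  cat(sprintf(
    "  beta = %.4f (SE %.4f), gamma_hat = %.5f (Fisher SE %.5f)\n",
    x$beta, x$se_beta, x$gamma_hat, x$se_gamma
  ))
  if (length(x$delta)) {
    cat(
      "  bias covariates:",
      paste(sprintf("%s = %.4f", names(x$delta), x$delta), collapse = ", "),
      "\n"
    )
  }
  cat(sprintf(
    "  %d observations in %d studies, logLik = %.3f\n",
    x$n_obs, x$n_studies, x$logLik
  ))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bop_mixed_fit <- function(x, ...) {
  est <- c(signal = x$beta, x$delta)
  se <- c(signal = x$se_beta, x$se_delta)
  tibble::tibble(
    term = names(est),
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = 2 * pnorm(-abs(unname(est / se)))
  )
}

#' @exportS3Method generics::glance
glance.bop_mixed_fit <- function(x, ...) {
  tibble::tibble(
    beta = x$beta, se_beta = x$se_beta,
    gamma_hat = x$gamma_hat, se_gamma = x$se_gamma,
    logLik = x$logLik, n_obs = x$n_obs, n_studies = x$n_studies
  )
}
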
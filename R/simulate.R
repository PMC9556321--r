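#' True exposure-response curve used by the synthetic cohort generator
#'
#' A saturating exponential `theta_max * (1 - exp(-x / tau))`: log RR is 0
#' at zero exposure and approaches `theta_max` asymptotically, reproducing
#' the protective-risk shape in which the largest risk difference sits
#' between zero and low consumption.
#'
#' @param x Exposure in g/day (>= 0).
#' @param theta_max Asymptotic log RR (e.g. -0.30 for a protective curve).
#' @param tau Exposure scale (g/day, > 0).
#' @return Log RR at `x`.
#' @export
true_log_rr <- function(x, theta_max = -0.30, tau = 75) {
  if (any(x < 0)) abort("Exposure `x` must be non-negative.")
  if (tau <= 0) abort("`tau` must be positive.")
  theta_max * (1 - exp(-x / tau))
}

# exact interval average of the true curve (closed form)
.true_avg <- function(lower, upper, theta_max, tau) {
  theta_max * (1 - tau * (exp(-lower / tau) - exp(-upper / tau)) / (upper - lower))
}

#' Configuration for the synthetic cohort generator
#'
#' Defaults emulate the extracted dose-response literature the analysis is
#' designed for: a modest number of prospective cohorts, 3-5 quantile-based
#' consumption categories each compared against the lowest-consumption
#' reference, a monotone protective true curve, multiplicative study-level
#' random slopes, CI-derived standard errors, and optional study-design bias
#' effects and small-study publication censoring.
#'
#' @param n_studies Number of cohorts (>= 2).
#' @param categories_per_study Number of exposure categories per study; a
#'   single count or a vector of candidate counts sampled per study.
#' @param exposure_shape,exposure_scale Gamma parameters of the right-skewed
#'   per-study consumption distribution (g/day).
#' @param theta_max Asymptotic true log RR.
#' @param tau Exposure scale of the true curve (g/day).
#' @param gamma_true Between-study variance of the random slope (>= 0).
#' @param sigma_range Range from which observation SEs are drawn uniformly.
#' @param delta_true Named numeric vector of bias effects on the signal
#'   scale (each scales the true signal by `1 + delta` when the covariate is
#'   1), one per `cv_*` covariate; use effect 0 to generate a null
#'   covariate.
#' @param censor_prob Probability that a small-study, null-consistent
#'   observation is suppressed (see [apply_publication_censoring()]).
#' @param small_study_n Sample-size threshold defining a small study.
#' @param sigma_mode `"uniform"` (default) draws SEs from `sigma_range`;
#'   `"events"` derives them from simulated event counts,
#'   `sigma ~ sqrt(1/E_alt + 1/E_ref)`.
#' @param random_effect `"slope"` (default) applies the study effect
#'   multiplicatively to the signal; `"intercept"` adds it to the log RR.
#' @param seed Integer seed; identical configurations reproduce identical
#'   tables.
#' @return A list of class `bop_sim_config`.
#' @export
sim_config <- function(n_studies = 15, categories_per_study = 4:5,
                       exposure_shape = 2, exposure_scale = 100,
                       theta_max = -0.30, tau = 75,
                       gamma_true = 0.01, sigma_range = c(0.05, 0.20),
                       delta_true = NULL, censor_prob = 0,
                       small_study_n = 10000,
                       sigma_mode = c("uniform", "events"),
                       random_effect = c("slope", "intercept"),
                       seed = 1L) {
  sigma_mode <- match.arg(sigma_mode)
  random_effect <- match.arg(random_effect)
  if (n_studies < 2) abort("`n_studies` must be at least 2.")
  if (gamma_true < 0) abort("`gamma_true` must be non-negative.")
  if (tau <= 0) abort("`tau` must be positive.")
  if (censor_prob < 0 || censor_prob > 1) abort("`censor_prob` must lie in [0, 1].")
  if (any(categories_per_study < 2)) {
    abort("`categories_per_study` must be at least 2.")
  }
  if (length(sigma_range) != 2 || any(sigma_range <= 0) ||
      sigma_range[1] > sigma_range[2]) {
    abort("`sigma_range` must be an increasing pair of positive SEs.")
  }
  if (!is.null(delta_true)) {
    if (is.null(names(delta_true)) || any(!nzchar(names(delta_true)))) {
      abort("`delta_true` must be a named numeric vector.")
    }
    names(delta_true) <- ifelse(
      grepl("^cv_", names(delta_true)),
      names(delta_true), paste0("cv_", names(delta_true))
    )
  }
  structure(
    list(
      n_studies = n_studies, categories_per_study = categories_per_study,
      exposure_shape = exposure_shape, exposure_scale = exposure_scale,
      theta_max = theta_max, tau = tau, gamma_true = gamma_true,
      sigma_range = sigma_range, delta_true = delta_true,
      censor_prob = censor_prob, small_study_n = small_study_n,
      sigma_mode = sigma_mode, random_effect = random_effect,
      seed = as.integer(seed)
    ),
    class = "bop_sim_config"
  )
}

#' Simulate a study table of dose-response comparisons
#'
#' Each cohort draws a right-skewed consumption distribution; category
#' bounds sit at its quantiles with the lowest-consumption category as
#' reference. Each higher category contributes one observation
#' `y = (1 + u_s + sum(delta_c x_c)) * (mean true log RR over the category -
#' mean over the reference) + eps`, with `u_s ~ N(0, gamma_true)` and
#' `eps ~ N(0, sigma^2)`; the reported CI is back-computed from sigma. All
#' realized random effects and assignments are recorded in the returned
#' truth object.
#'
#' @param config A [sim_config()].
#' @return A list with elements `table` (a validated study table) and
#'   `truth` (class `bop_sim_truth`: the config, per-study random effects,
#'   covariate assignments, the true-curve parameters, and a censoring
#'   mask slot).
#' @export
simulate_study_table <- function(config) {
  if (!inherits(config, "bop_sim_config")) {
    abort("`config` must be created by `sim_config()`.")
  }
  withr::local_seed(config$seed)
  cov_names <- names(config$delta_true)

  study_rows <- vector("list", config$n_studies)
  obs_rows <- vector("list", config$n_studies)
  for (s in seq_len(config$n_studies)) {
    sid <- sprintf("study_%02d", s)
    J <- if (length(config$categories_per_study) == 1) {
      config$categories_per_study
    } else {
      sample(config$categories_per_study, 1)
    }
    scale_s <- config$exposure_scale * exp(rnorm(1, 0, 0.2))
    probs <- c(seq(0, (J - 1) / J, by = 1 / J), 0.975)
    bounds <- stats::qgamma(probs, shape = config$exposure_shape, scale = scale_s)
    if (any(diff(bounds) <= 0)) {
      abort(paste0(
        "Degenerate consumption quantile ladder for ", sid,
        "; check `exposure_shape`/`exposure_scale`."
      ))
    }
    u_s <- rnorm(1, 0, sqrt(config$gamma_true))
    n_s <- max(100L, round(rlnorm(1, log(2e4), 1)))
    x_s <- if (length(cov_names)) {
      setNames(rbinom(length(cov_names), 1, 0.5), cov_names)
    } else {
      setNames(numeric(0), character(0))
    }
    followup <- round(runif(1, 5, 20), 1)
    ref <- bounds[1:2]
    s_ref <- .true_avg(ref[1], ref[2], config$theta_max, config$tau)

    rows <- vector("list", J - 1)
    for (j in 2:J) {
      alt <- bounds[c(j, j + 1)]
      s_true <- .true_avg(alt[1], alt[2], config$theta_max, config$tau) - s_ref
      if (config$sigma_mode == "events") {
        rate <- 0.05
        e_ref <- max(5, round(n_s / J * rate))
        e_alt <- max(5, round(n_s / J * rate * exp(s_true)))
        sigma <- sqrt(1 / e_alt + 1 / e_ref)
        events <- e_alt
      } else {
        sigma <- runif(1, config$sigma_range[1], config$sigma_range[2])
        events <- NA_real_
      }
      signal_part <- if (config$random_effect == "slope") {
        (1 + u_s) * s_true
      } else {
        s_true + u_s
      }
      # bias effects scale the signal, mirroring the analysis model: a zero
      # signal (identical exposure comparison) stays null under any design
      y <- signal_part + sum(config$delta_true * x_s[cov_names]) * s_true +
        rnorm(1, 0, sigma)
      row <- tibble::tibble(
        study_id = sid, outcome = "synthetic_outcome",
        ref_lower = ref[1], ref_upper = ref[2],
        alt_lower = alt[1], alt_upper = alt[2],
        measure_type = "RR",
        effect = exp(y),
        ci_lower = exp(y - Z975 * sigma),
        ci_upper = exp(y + Z975 * sigma),
        sample_size = n_s, events = events, followup_years = followup
      )
      for (cn in cov_names) row[[cn]] <- x_s[[cn]]
      rows[[j - 1]] <- row
    }
    obs_rows[[s]] <- dplyr::bind_rows(rows)
    study_rows[[s]] <- tibble::tibble(
      study_id = sid, u = u_s, sample_size = n_s,
      n_categories = J, exposure_scale = scale_s,
      !!!as.list(x_s)
    )
  }

  table <- as_study_table(dplyr::bind_rows(obs_rows))
  truth <- structure(
    list(
      config = config,
      studies = dplyr::bind_rows(study_rows),
      theta_max = config$theta_max, tau = config$tau,
      gamma_true = config$gamma_true, delta_true = config$delta_true,
      censor_mask = rep(FALSE, nrow(table))
    ),
    class = "bop_sim_truth"
  )
  list(table = table, truth = truth)
}

#' Suppress small-study null-consistent observations
#'
#' Emulates publication and reporting bias: observations from studies with
#' `sample_size < small_study_n` whose standardized effect
#' `|log_rr / se_log_rr|` falls short of the two-sided 95% significance
#' threshold are dropped with probability `censor_prob`. The realized
#' censoring mask (TRUE = suppressed) is recorded in the truth object.
#'
#' @param table A study table produced by [simulate_study_table()].
#' @param truth The matching `bop_sim_truth`.
#' @param censor_prob Suppression probability in `[0, 1]`.
#' @param small_study_n Sample-size threshold defining a small study.
#' @param seed Integer seed for the suppression draws.
#' @return A list with the censored `table` and updated `truth`.
#' @export
apply_publication_censoring <- function(table, truth, censor_prob,
                                        small_study_n, seed = 1L) {
  table <- as_study_table(table)
  if (censor_prob < 0 || censor_prob > 1) abort("`censor_prob` must lie in [0, 1].")
  withr::local_seed(as.integer(seed))
  eligible <- table$sample_size < small_study_n &
    abs(table$log_rr / table$se_log_rr) < Z975
  drop <- eligible & runif(nrow(table)) < censor_prob
  if (all(drop)) {
    abort("Publication censoring suppressed every observation; empty table.")
  }
  truth$censor_mask <- drop
  list(table = table[!drop, , drop = FALSE], truth = truth)
}
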
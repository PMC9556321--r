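#' Configuration for the full evidence-scoring pipeline
#'
#' Collects every tunable of the analysis with defaults matching the
#' package's standard protective-risk configuration. The configuration
#' round-trips through YAML via [write_pipeline_config()] /
#' [read_pipeline_config()].
#'
#' @param input Path to a study-table CSV (optional when data are passed to
#'   [run_pipeline()] directly).
#' @param outcome Optional outcome label (checked against the table).
#' @param interior_knots Interior knots in g/day; `NULL` for quantile-based
#'   defaults.
#' @param degree Spline degree (default 2).
#' @param monotone_decreasing,linear_right_tail Shape constraints.
#' @param trim_fraction Trimming proportion (default 0.10).
#' @param het_level Heterogeneity quantile level for `gamma*` (default 0.95).
#' @param covariates Candidate bias covariates; `NULL` uses every `cv_*`
#'   column.
#' @param alpha Covariate-selection significance level.
#' @param p_lo,p_hi Exposure percentiles for ROS averaging.
#' @param tmrel_pct TMREL percentile.
#' @param grid_n Risk-curve grid resolution.
#' @param out_dir Output directory (optional; no files written when `NULL`).
#' @param seed Integer seed recorded for provenance.
#' @return A list of class `bop_pipeline_config`.
#' @export
pipeline_config <- function(input = NULL, outcome = NULL,
                            interior_knots = NULL, degree = 2,
                            monotone_decreasing = TRUE,
                            linear_right_tail = TRUE,
                            trim_fraction = 0.10, het_level = 0.95,
                            covariates = NULL, alpha = 0.05,
                            p_lo = 15, p_hi = 85, tmrel_pct = 85,
                            grid_n = 101, out_dir = NULL, seed = 1L) {
  structure(
    list(
      input = input, outcome = outcome, interior_knots = interior_knots,
      degree = degree, monotone_decreasing = monotone_decreasing,
      linear_right_tail = linear_right_tail,
      trim_fraction = trim_fraction, het_level = het_level,
      covariates = covariates, alpha = alpha,
      p_lo = p_lo, p_hi = p_hi, tmrel_pct = tmrel_pct,
      grid_n = grid_n, out_dir = out_dir, seed = as.integer(seed)
    ),
    class = "bop_pipeline_config"
  )
}

#' @rdname pipeline_config
#' @param config A `bop_pipeline_config`.
#' @param path YAML file path.
#' @export
write_pipeline_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname pipeline_config
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(pipeline_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)))
  })
}

#' Run the full burden-of-proof pipeline
#'
#' Executes, in order: signal-curve fitting with trimming, bias-covariate
#' selection, the mixed-effects meta-regression, the Fisher-corrected
#' heterogeneity quantile, risk-curve prediction with conventional and
#' conservative UIs, the BPRF / ROS / star rating, Egger's regression, and
#' the TMREL. When `config$out_dir` is set, writes `risk_curve.csv`,
#' `funnel.csv`, `score.json`, `config.yaml`, and an audit `log.json`
#' recording the trim mask, selected covariates, and all fitted parameters.
#' Deterministic given the configuration and input.
#'
#' @param config A [pipeline_config()].
#' @param data Optional study table, overriding `config$input`.
#' @return An object of class `bop_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), data = NULL) {
  if (!inherits(config, "bop_pipeline_config")) {
    abort("`config` must be created by `pipeline_config()`.")
  }
  table <- .stage("read", {
    if (!is.null(data)) {
      as_study_table(data)
    } else if (!is.null(config$input)) {
      read_study_table(config$input)
    } else {
      abort("No input: supply `data` or set `config$input`.")
    }
  })
  if (!is.null(config$outcome) && !all(table$outcome == config$outcome)) {
    abort(paste0("Table outcome does not match configured `", config$outcome, "`."))
  }

  signal_fit <- .stage("fit_signal", {
    spec <- spline_spec(
      interior_knots = config$interior_knots %||% default_knots(table),
      domain = c(0, max(table$alt_upper, table$ref_upper)),
      degree = config$degree,
      monotone_decreasing = config$monotone_decreasing,
      linear_right_tail = config$linear_right_tail
    )
    fit_signal(table, spec, trim_fraction = config$trim_fraction)
  })
  selected <- .stage("select_bias_covariates", {
    select_bias_covariates(table, signal_fit,
      candidates = config$covariates %||% covariate_names(table),
      alpha = config$alpha
    )
  })
  mixed_fit <- .stage("fit_linear_mixed", {
    fit_linear_mixed(table, signal_fit, covariates = selected)
  })
  gamma_star <- .stage("gamma_upper_quantile", {
    gamma_upper_quantile(mixed_fit, level = config$het_level)
  })
  risk_curve <- .stage("predict_risk_curve", {
    predict_risk_curve(mixed_fit, signal_fit,
      grid = seq(0, signal_fit$spec$domain[2], length.out = config$grid_n),
      gamma_star = gamma_star
    )
  })
  score <- .stage("evidence_score", {
    evidence_score(mixed_fit, signal_fit, table, het_level = config$het_level)
  })
  funnel <- .stage("residual_table", {
    residual_table(table, mixed_fit, signal_fit, gamma_star)
  })
  egger <- .stage("egger_regression", egger_regression(funnel))
  tmrel <- .stage("compute_tmrel", compute_tmrel(table, pct = config$tmrel_pct))

  report <- structure(
    list(
      config = config, table = table, signal_fit = signal_fit,
      selected_covariates = selected, mixed_fit = mixed_fit,
      gamma_star = gamma_star, risk_curve = risk_curve,
      score = score, funnel = funnel, egger = egger, tmrel = tmrel
    ),
    class = "bop_report"
  )
  if (!is.null(config$out_dir)) .write_report(report)
  report
}

.score_list <- function(report) {
  s <- report$score
  list(
    ros = s$ros, stars = s$stars, direction = s$direction,
    beta = report$mixed_fit$beta, se_beta = report$mixed_fit$se_beta,
    gamma_hat = report$mixed_fit$gamma_hat,
    se_gamma = report$mixed_fit$se_gamma,
    gamma_star = s$gamma_star, beta_conservative = s$beta_conservative,
    p15 = s$p15, p85 = s$p85,
    tmrel_lower = report$tmrel$lower, tmrel_upper = report$tmrel$upper,
    egger_slope = report$egger$slope, egger_p = report$egger$p_value,
    egger_flagged = report$egger$flagged,
    selected_covariates = as.list(report$selected_covariates)
  )
}

.write_report <- function(report) {
  dir.create(report$config$out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(report$config$out_dir, f)
  readr::write_csv(tibble::as_tibble(report$risk_curve), p("risk_curve.csv"),
    progress = FALSE
  )
  readr::write_csv(report$funnel, p("funnel.csv"), progress = FALSE)
  jsonlite::write_json(.score_list(report), p("score.json"),
    auto_unbox = TRUE, digits = NA
  )
  write_pipeline_config(report$config, p("config.yaml"))
  log <- c(.score_list(report), list(
    trim_mask_kept = report$signal_fit$trim_mask,
    trim_iterations = report$signal_fit$iterations,
    interior_knots = report$signal_fit$spec$interior_knots,
    n_obs = nrow(report$table),
    n_studies = length(unique(report$table$study_id)),
    seed = report$config$seed
  ))
  jsonlite::write_json(log, p("log.json"), auto_unbox = TRUE, digits = NA)
  invisible(report)
}

#' @export
print.bop_report <- function(x, ...) {
  pc <- percent_change(x$risk_curve, 0, (x$tmrel$lower + x$tmrel$upper) / 2)
  cat("Burden-of-proof pipeline report\n")
  cat(sprintf(
    "  %d observations, %d studies, outcome `%s`\n",
    nrow(x$table), length(unique(x$table$study_id)), x$table$outcome[1]
  ))
  cat(sprintf(
    "  beta = %.4f (SE %.4f), gamma_hat = %.5f, gamma* = %.5f\n",
    x$mixed_fit$beta, x$mixed_fit$se_beta, x$mixed_fit$gamma_hat, x$gamma_star
  ))
  cat(sprintf(
    "  ROS = %s (%d star%s, %s), averaged over [%.1f, %.1f] g/day\n",
    .format_ros(x$score$ros), x$score$stars,
    if (x$score$stars > 1) "s" else "", x$score$direction,
    x$score$p15, x$score$p85
  ))
  cat(sprintf(
    "  TMREL %.0f-%.0f g/day; risk at TMREL midpoint %.1f%% (%.1f-%.1f) lower than at 0 g/day\n",
    x$tmrel$lower, x$tmrel$upper,
    pc$mean, pc$conservative_lo, pc$conservative_hi
  ))
  cat(sprintf(
    "  Egger slope %.3f, p = %.3g (%s)\n",
    x$egger$slope, x$egger$p_value,
    if (x$egger$flagged) "flagged" else "not flagged"
  ))
  if (length(x$selected_covariates)) {
    cat(
      "  bias covariates:",
      paste(x$selected_covariates, collapse = ", "), "\n"
    )
  }
  invisible(x)
}

#' Sensitivity analyses around a pipeline configuration
#'
#' Reruns the pipeline (a) without trimming and (b) optionally with a named
#' bias covariate forced into the meta-regression regardless of the
#' selection step, and reports ROS deltas against the base analysis.
#'
#' @param config A [pipeline_config()].
#' @param data Optional study table, overriding `config$input`.
#' @param forced_covariate Optional `cv_*` column to force into the model.
#' @return A tibble of class `bop_sensitivity` with one row per analysis:
#'   `analysis`, `ros`, `stars`, `delta_ros`.
#' @export
sensitivity_suite <- function(config = pipeline_config(), data = NULL,
                              forced_covariate = NULL) {
  base <- run_pipeline(config, data)
  no_out <- config
  no_out$out_dir <- NULL

  cfg_notrim <- no_out
  cfg_notrim$trim_fraction <- 0
  notrim <- run_pipeline(cfg_notrim, data)

  rows <- list(
    tibble::tibble(
      analysis = "base", ros = base$score$ros,
      stars = base$score$stars, delta_ros = 0
    ),
    tibble::tibble(
      analysis = "no_trimming", ros = notrim$score$ros,
      stars = notrim$score$stars,
      delta_ros = notrim$score$ros - base$score$ros
    )
  )
  if (!is.null(forced_covariate)) {
    if (!forced_covariate %in% names(base$table)) {
      abort(paste0("Forced covariate `", forced_covariate, "` not in table."))
    }
    forced <- union(base$selected_covariates, forced_covariate)
    mixed <- fit_linear_mixed(base$table, base$signal_fit, covariates = forced)
    score <- evidence_score(mixed, base$signal_fit, base$table,
      het_level = config$het_level
    )
    rows <- c(rows, list(tibble::tibble(
      analysis = paste0("forced_", forced_covariate), ros = score$ros,
      stars = score$stars, delta_ros = score$ros - base$score$ros
    )))
  }
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("bop_sensitivity", class(out)), base = base)
}
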
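test_that("an exact signal fit yields beta = 1 and zero heterogeneity", {
  tb <- make_linear_table(slope = -5e-4, se = 0.05)
  sfit <- fit_signal(tb, trim_fraction = 0)
  # rebuild the table so observed log effects equal the fitted signal exactly
  tb2 <- tb
  tb2$effect <- exp(sfit$fitted_signal)
  tb2$ci_lower <- tb2$effect * exp(-qnorm(0.975) * 0.05)
  tb2$ci_upper <- tb2$effect * exp(qnorm(0.975) * 0.05)
  fit <- fit_linear_mixed(tb2, sfit)
  expect_equal(fit$beta, 1, tolerance = 1e-6)
  expect_equal(fit$gamma_hat, 0)
  expect_length(fit$delta, 0)
})

test_that("the balanced two-study case matches the closed-form solution", {
  aux <- make_linear_table(slope = -1e-3)
  sfit <- fit_signal(aux, trim_fraction = 0)
  tb <- tibble::tibble(
    study_id = c("s1", "s2"), outcome = "fixture_outcome",
    ref_lower = 0, ref_upper = 100, alt_lower = 150, alt_upper = 250,
    measure_type = "RR", effect = 1, ci_lower = 1, ci_upper = 1,
    sample_size = 1e4, events = NA_real_, followup_years = 10
  )
  sigma <- 0.05
  s <- predict_signal(sfit, tb[1, ])
  y <- c(1.5, 0.5) * s
  tb$effect <- exp(y)
  tb$ci_lower <- exp(y - qnorm(0.975) * sigma)
  tb$ci_upper <- exp(y + qnorm(0.975) * sigma)
  fit <- fit_linear_mixed(tb, sfit)

  # hand-derived GLS/ML for two balanced observations with equal sigma:
  # beta = mean(y)/s; V = (y1 - y2)^2 / 4; gamma = (V - sigma^2)/s^2
  beta_cf <- mean(y) / s
  V_cf <- (y[1] - y[2])^2 / 4
  gamma_cf <- max(0, (V_cf - sigma^2) / s^2)
  expect_equal(fit$beta, beta_cf, tolerance = 1e-6)
  expect_equal(fit$gamma_hat, gamma_cf, tolerance = 1e-5)
  expect_equal(fit$se_beta, sqrt(V_cf / (2 * s^2)), tolerance = 1e-4)
})

test_that("the profile likelihood is locally optimal at gamma_hat", {
  sim <- default_sim(seed = 43, n_studies = 25, gamma_true = 0.02)
  sfit <- fit_signal(sim$table)
  fit <- fit_linear_mixed(sim$table, sfit)
  mf <- fit$model_frame
  Fd <- cbind(signal = mf$signal)
  w <- 1 / mf$sigma^2
  blocks <- split(seq_len(nrow(mf)), mf$study_id)
  ll <- function(g) bopmeta:::.mixed_gls(Fd, mf$y, w, blocks, g)$loglik
  eps <- 1e-6
  expect_gte(ll(fit$gamma_hat), ll(fit$gamma_hat + eps))
  if (fit$gamma_hat > eps) {
    expect_gte(ll(fit$gamma_hat), ll(fit$gamma_hat - eps))
  }
})

test_that("single-study tables flag heterogeneity as inestimable", {
  tb <- make_linear_table(slope = -5e-4)
  tb$study_id <- "only_one"
  sfit <- fit_signal(tb, trim_fraction = 0)
  fit <- fit_linear_mixed(tb, sfit)
  expect_equal(fit$gamma_hat, 0)
  expect_false(fit$gamma_estimable)
  expect_error(gamma_upper_quantile(fit), "unavailable")
})

test_that("collinear covariates raise a rank-deficiency error", {
  sim <- default_sim(seed = 47, delta_true = c(cv_a = 0.2))
  tb <- sim$table
  tb$cv_b <- tb$cv_a
  sfit <- fit_signal(tb)
  expect_error(
    fit_linear_mixed(tb, sfit, covariates = c("cv_a", "cv_b")),
    "collinear"
  )
})

test_that("gamma* is the Fisher-information upper quantile", {
  fake <- structure(
    list(gamma_hat = 0.01, se_gamma = 0.005),
    class = "bop_mixed_fit"
  )
  expect_equal(gamma_upper_quantile(fake), 0.018224, tolerance = 1e-4)
  fake$se_gamma <- 0
  expect_equal(gamma_upper_quantile(fake), fake$gamma_hat)
  fake$se_gamma <- NULL
  expect_error(gamma_upper_quantile(fake), "unavailable")
})

test_that("delta estimates flip sign under covariate relabelling", {
  sim <- default_sim(seed = 53, delta_true = c(cv_a = 0.3))
  sfit <- fit_signal(sim$table)
  fit <- fit_linear_mixed(sim$table, sfit, covariates = "cv_a")
  flipped <- sim$table
  flipped$cv_a <- 1 - flipped$cv_a
  fit2 <- fit_linear_mixed(flipped, sfit, covariates = "cv_a")
  expect_equal(fit2$delta[["cv_a"]], -fit$delta[["cv_a"]], tolerance = 1e-6)
  expect_equal(fit2$beta, fit$beta + fit$delta[["cv_a"]], tolerance = 1e-6)
})

test_that("covariate selection finds planted effects and skips constants", {
  expect_identical(
    select_bias_covariates(signal_fit = fit_signal(make_linear_table())),
    character(0)
  )
  hits <- 0L
  for (r in 1:20) {
    sim <- simulate_study_table(sim_config(
      n_studies = 25, gamma_true = 0, sigma_range = c(0.03, 0.06),
      delta_true = c(cv_bias = 0.5), seed = 600 + r
    ))
    sfit <- fit_signal(sim$table)
    sel <- select_bias_covariates(sim$table, sfit, candidates = "cv_bias")
    hits <- hits + ("cv_bias" %in% sel)
  }
  expect_gte(hits, 19)

  sim <- default_sim(seed = 59, delta_true = c(cv_a = 0.4))
  tb <- sim$table
  tb$cv_const <- 1
  sfit <- fit_signal(tb)
  expect_warning(
    select_bias_covariates(tb, sfit, candidates = "cv_const"),
    "constant"
  )
})

test_that("null covariates are selected at roughly the nominal rate", {
  hits <- 0L
  n_rep <- 300L
  for (r in seq_len(n_rep)) {
    sim <- simulate_study_table(sim_config(
      n_studies = 15, delta_true = c(cv_null = 0), seed = 1000 + r
    ))
    sfit <- fit_signal(sim$table)
    sel <- select_bias_covariates(sim$table, sfit, candidates = "cv_null")
    hits <- hits + length(sel)
  }
  rate <- hits / n_rep
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("risk curves anchor at zero and order their intervals", {
  fake <- structure(
    list(beta = 1, se_beta = 0.1, gamma_hat = 0, se_gamma = 0.01),
    class = "bop_mixed_fit"
  )
  lin <- curve_linear(-0.001, x_max = 400)
  rc <- predict_risk_curve(fake,
    signal_fit = lin, grid = c(0, 200),
    gamma_star = 0
  )
  expect_equal(unlist(rc[1, -1]), setNames(
    c(0, 1, 0, 0, 0, 0),
    names(unlist(rc[1, -1]))
  ))
  expect_equal(rc$log_rr[2], -0.2)
  expect_equal(rc$conventional_lo[2], -0.2392, tolerance = 1e-4)
  expect_equal(rc$conventional_hi[2], -0.1608, tolerance = 1e-4)

  rc2 <- predict_risk_curve(fake,
    signal_fit = lin, grid = seq(0, 400, 50),
    gamma_star = 0.01
  )
  nz <- rc2$exposure > 0
  expect_true(all(rc2$conservative_lo[nz] < rc2$conventional_lo[nz]))
  expect_true(all(rc2$conservative_hi[nz] > rc2$conventional_hi[nz]))
})
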
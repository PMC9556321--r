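fake_fit <- function(beta, se_beta) {
  structure(
    list(beta = beta, se_beta = se_beta, gamma_hat = 0, se_gamma = 0),
    class = "bop_mixed_fit"
  )
}

test_that("the BPRF coefficient is the null-ward quantile shift", {
  lin <- curve_linear(-0.001)
  b0 <- compute_bprf(fake_fit(1, 0), lin, gamma_star = 0, "protective")
  expect_equal(b0$beta_cons, 1) # no uncertainty: BPRF is the mean curve
  expect_equal(b0$grid$log_bprf, b0$grid$log_rr)

  b1 <- compute_bprf(fake_fit(1, 0.1), lin, gamma_star = 0, "protective")
  expect_equal(b1$beta_cons, 0.835515, tolerance = 1e-5)

  b2 <- compute_bprf(fake_fit(0.5, 0.4), lin, gamma_star = 0.09, "protective")
  expect_equal(b2$beta_cons, -0.322427, tolerance = 1e-5)
  # BPRF opposite null: the score goes negative, one star
  ros <- compute_ros(b2, 50, 350, "protective")
  expect_lt(ros, 0)
  expect_equal(star_rating(ros, "protective"), 1L)

  expect_error(compute_bprf(fake_fit(1, 0.1), lin, NULL, "protective"), "gamma_star")
})

test_that("exposure percentiles use the interpolation convention", {
  tb <- make_midpoint_table(seq(10, 100, by = 10), half = 5, ref_width = 5)
  expect_equal(
    exposure_percentiles(tb),
    c(p15 = 23.5, p85 = 86.5)
  )
  one <- make_midpoint_table(150)
  expect_equal(unname(exposure_percentiles(one)), c(150, 150))
  sim <- default_sim(seed = 61)
  pc <- exposure_percentiles(sim$table)
  expect_lte(pc[[1]], pc[[2]])
})

test_that("the ROS is the signed exposure-averaged log-BPRF", {
  expect_equal(compute_ros(log(0.858), 0, 100, "protective"), -log(0.858))
  expect_equal(round(compute_ros(log(0.858), 0, 100, "protective"), 2), 0.15)
  expect_equal(round(compute_ros(log(0.879), 0, 100, "protective"), 2), 0.13)
  expect_equal(compute_ros(0, 0, 100, "protective"), 0)
  f <- function(x) -0.15 * (1 - exp(-x / 150))
  expect_equal(compute_ros(f, 80, 280, "protective"), 0.10140, tolerance = 1e-4)
  # quadrature cross-check of the spline path
  lin <- curve_linear(-0.001)
  bprf <- compute_bprf(fake_fit(0.9, 0.05), lin, gamma_star = 0.001, "protective")
  g <- function(x) bprf$beta_cons * bopmeta:::.curve_eval(lin, x)
  expect_equal(
    compute_ros(bprf, 80, 280),
    -integrate(g, 80, 280, rel.tol = 1e-10)$value / 200,
    tolerance = 1e-8
  )
  expect_error(compute_ros(log(0.9), 200, 100), "p15 <= p85")
})

test_that("star ratings reproduce the published ROS pairs and cuts", {
  expect_equal(star_rating(0.15, "protective"), 3L)
  expect_equal(star_rating(0.016, "protective"), 2L)
  expect_equal(star_rating(0.001, "protective"), 2L)
  expect_equal(star_rating(-0.031, "protective"), 1L)
  # boundary: d exactly 13% is still two stars (cuts are right-closed)
  expect_equal(star_rating(-log(0.87), "protective"), 2L)
  expect_equal(star_rating(-log(0.87) + 1e-9, "protective"), 3L)
  expect_equal(star_rating(-log(0.54) + 1e-9, "protective"), 5L)
  # harmful cuts use the printed percent-increase thresholds
  expect_equal(star_rating(log(1.15), "harmful"), 2L)
  expect_equal(star_rating(log(1.15) + 1e-9, "harmful"), 3L)
  expect_equal(star_rating(log(1.85) + 1e-9, "harmful"), 5L)
  expect_equal(star_rating(-0.01, "harmful"), 1L)
})

test_that("conservative scores shrink toward null relative to the mean curve", {
  lin <- curve_linear(-0.001)
  mean_score <- compute_ros(
    compute_bprf(fake_fit(1, 0), lin, 0, "protective"), 50, 300
  )
  cons_score <- compute_ros(
    compute_bprf(fake_fit(1, 0.08), lin, 0.01, "protective"), 50, 300
  )
  expect_lte(cons_score, mean_score)
})

test_that("the TMREL follows the 85th-percentile rule over top categories", {
  single <- make_midpoint_table(c(150, 250, 350), half = 50)
  tm <- compute_tmrel(single)
  expect_equal(tm$lower, 300)
  expect_equal(tm$upper, 350)

  lowers <- c(100, 200, 250, 300, 350)
  mids <- c(150, 250, 300, 350, 450)
  tables <- purrr::map2(lowers, mids, function(lo, mid) {
    tb <- make_midpoint_table(c(30, mid), half = 5)
    tb$study_id <- paste0("study_", lo)
    tb$alt_lower[2] <- lo
    tb$alt_upper[2] <- 2 * mid - lo
    tb
  })
  tm5 <- compute_tmrel(dplyr::bind_rows(tables))
  expect_equal(tm5$lower, 320)
  expect_equal(tm5$upper, 390)
  expect_lte(tm5$lower, tm5$upper)
  expect_error(compute_tmrel(list()), "No studies")
})

test_that("percent changes transform and chain on the RR scale", {
  fake <- fake_fit(1, 0.05)
  lin <- curve_linear(-0.001)
  rc <- predict_risk_curve(fake, signal_fit = lin, gamma_star = 0.002)
  expect_equal(percent_change(rc, 100, 100)$mean, 0)
  expect_equal(percent_change(rc, 0, 100)$mean, 9.5163, tolerance = 1e-4)
  d1 <- percent_change(rc, 0, 100)$mean / 100
  d2 <- percent_change(rc, 100, 200)$mean / 100
  d02 <- percent_change(rc, 0, 200)$mean / 100
  expect_equal(d02, 1 - (1 - d1) * (1 - d2), tolerance = 1e-12)
  pc <- percent_change(rc, 0, 300)
  expect_lte(pc$conservative_lo, pc$conventional_lo)
  expect_gte(pc$conservative_hi, pc$conventional_hi)
})

test_that("evidence_score assembles a coherent summary", {
  sim <- default_sim(seed = 67)
  sfit <- fit_signal(sim$table)
  fit <- fit_linear_mixed(sim$table, sfit)
  sc <- evidence_score(fit, sfit, sim$table)
  expect_s3_class(sc, "bop_evidence_score")
  expect_equal(sc$direction, "protective")
  expect_true(sc$stars %in% 1:5)
  expect_lte(sc$p15, sc$p85)
  expect_gte(sc$gamma_star, fit$gamma_hat)
  td <- tidy(sc)
  expect_identical(td$term[1], "ros")
})
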
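test_that("the true curve anchors at zero and saturates at theta_max", {
  expect_equal(true_log_rr(0, -0.30, 75), 0)
  expect_equal(true_log_rr(1e7, -0.30, 75), -0.30)
  expect_equal(true_log_rr(75, -0.30, 75), -0.18964, tolerance = 1e-4)
  expect_error(true_log_rr(-1), "non-negative")
})

test_that("simulation is deterministic and sized by design", {
  cfg <- sim_config(n_studies = 10, categories_per_study = 4, seed = 7)
  a <- simulate_study_table(cfg)
  b <- simulate_study_table(cfg)
  expect_identical(a$table, b$table)
  expect_identical(a$truth$studies, b$truth$studies)
  # J categories yield J - 1 alternative-vs-reference comparisons
  expect_equal(nrow(a$table), 30)
  expect_equal(length(unique(a$table$study_id)), 10)
})

test_that("the noiseless limit reproduces interval-averaged true differences", {
  cfg <- sim_config(
    n_studies = 6, categories_per_study = 4, gamma_true = 0,
    sigma_range = c(1e-9, 1e-9), seed = 3
  )
  sim <- simulate_study_table(cfg)
  tb <- sim$table
  oracle <- vapply(seq_len(nrow(tb)), function(i) {
    f <- function(x) true_log_rr(x, cfg$theta_max, cfg$tau)
    a1 <- integrate(f, tb$alt_lower[i], tb$alt_upper[i], rel.tol = 1e-12)$value /
      (tb$alt_upper[i] - tb$alt_lower[i])
    a0 <- integrate(f, tb$ref_lower[i], tb$ref_upper[i], rel.tol = 1e-12)$value /
      (tb$ref_upper[i] - tb$ref_lower[i])
    a1 - a0
  }, numeric(1))
  expect_equal(tb$log_rr, oracle, tolerance = 1e-6)
})

test_that("noise is centred: precision-weighted mean error vanishes", {
  cfg <- sim_config(n_studies = 150, gamma_true = 0, seed = 21)
  sim <- simulate_study_table(cfg)
  tb <- sim$table
  f <- function(x) true_log_rr(x, cfg$theta_max, cfg$tau)
  avg <- function(lo, hi) {
    vapply(
      seq_along(lo),
      function(i) integrate(f, lo[i], hi[i])$value / (hi[i] - lo[i]),
      numeric(1)
    )
  }
  err <- tb$log_rr - (avg(tb$alt_lower, tb$alt_upper) - avg(tb$ref_lower, tb$ref_upper))
  w <- 1 / tb$se_log_rr^2
  wmean <- sum(w * err) / sum(w)
  se_wmean <- sqrt(1 / sum(w))
  expect_lt(abs(wmean), 3 * se_wmean)
})

test_that("per-study slope spread recovers gamma_true at large n", {
  g <- 0.04
  cfg <- sim_config(
    n_studies = 100, gamma_true = g, sigma_range = c(0.01, 0.02),
    seed = 31
  )
  sim <- simulate_study_table(cfg)
  # realized random slopes are recorded exactly
  expect_equal(var(sim$truth$studies$u), g, tolerance = 0.5)
  tb <- sim$table
  f <- function(x) true_log_rr(x, cfg$theta_max, cfg$tau)
  avg <- function(lo, hi) {
    vapply(
      seq_along(lo),
      function(i) integrate(f, lo[i], hi[i])$value / (hi[i] - lo[i]),
      numeric(1)
    )
  }
  s_true <- avg(tb$alt_lower, tb$alt_upper) - avg(tb$ref_lower, tb$ref_upper)
  slopes <- vapply(split(seq_len(nrow(tb)), tb$study_id), function(ix) {
    sum(tb$log_rr[ix] * s_true[ix]) / sum(s_true[ix]^2)
  }, numeric(1))
  expect_equal(var(slopes), g, tolerance = 0.5)
})

test_that("publication censoring suppresses small null-consistent results", {
  sim <- default_sim(seed = 5, n_studies = 12)
  unchanged <- apply_publication_censoring(sim$table, sim$truth,
    censor_prob = 0, small_study_n = 1e9, seed = 1
  )
  expect_identical(unchanged$table, sim$table)

  # a null curve where every observation is small and null-consistent
  null_cfg <- sim_config(
    n_studies = 5, theta_max = 0, gamma_true = 0,
    sigma_range = c(0.3, 0.4), seed = 9
  )
  null_sim <- simulate_study_table(null_cfg)
  expect_error(
    apply_publication_censoring(null_sim$table, null_sim$truth,
      censor_prob = 1, small_study_n = 1e9, seed = 1
    ),
    "empty"
  )

  # retained small-study observations over-represent large |y| under a null
  kept_z <- c()
  all_z <- c()
  for (r in 1:60) {
    s <- simulate_study_table(sim_config(
      n_studies = 8, theta_max = 0, gamma_true = 0, seed = 100 + r
    ))
    cens <- apply_publication_censoring(s$table, s$truth,
      censor_prob = 0.8, small_study_n = 1e9, seed = 200 + r
    )
    all_z <- c(all_z, abs(s$table$log_rr / s$table$se_log_rr))
    kept_z <- c(kept_z, abs(cens$table$log_rr / cens$table$se_log_rr))
  }
  expect_gt(mean(kept_z), mean(all_z))
})
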
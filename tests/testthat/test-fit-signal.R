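test_that("noiseless representable data are recovered exactly", {
  tb <- make_linear_table(slope = -5e-4)
  fit <- fit_signal(tb, trim_fraction = 0.10)
  truth <- predict_signal(curve_linear(-5e-4), tb)
  expect_equal(predict_signal(fit, tb), truth, tolerance = 1e-6)
})

test_that("all-null data give the zero curve with zero objective", {
  tb <- make_midpoint_table(seq(50, 350, by = 50), log_rr = 0)
  fit <- fit_signal(tb, trim_fraction = 0)
  expect_equal(fit$objective, 0)
  expect_equal(max(abs(signal_grid(fit)$log_rr)), 0)
})

test_that("planted gross outliers are exactly the trimmed observations", {
  tb <- make_linear_table(
    slope = -5e-4,
    midpoints = seq(30, 390, length.out = 20), se = 0.05
  )
  out_idx <- c(6, 14)
  tb$effect[out_idx] <- exp(log(tb$effect[out_idx]) + 10 * 0.05)
  tb$ci_lower[out_idx] <- tb$effect[out_idx] * exp(-qnorm(0.975) * 0.05)
  tb$ci_upper[out_idx] <- tb$effect[out_idx] * exp(qnorm(0.975) * 0.05)
  fit <- fit_signal(tb, trim_fraction = 0.10)
  expect_equal(which(!fit$trim_mask), out_idx)
  expect_equal(sum(!fit$trim_mask), floor(0.10 * nrow(tb)))
})

test_that("shape constraints hold exactly on the fitted curve", {
  sim <- default_sim(seed = 19)
  fit <- fit_signal(sim$table)
  grid <- signal_grid(fit, n = 200)
  expect_lte(max(diff(grid$log_rr)), 1e-10) # non-increasing
  expect_equal(grid$log_rr[1], 0) # f(0) = 0
  # zero curvature right of the last interior knot: derivative constant there
  tail_x <- seq(max(fit$spec$interior_knots), fit$spec$domain[2], length.out = 50)
  tail_y <- bopmeta:::.curve_eval(fit$curve, tail_x)
  second_diff <- diff(diff(tail_y))
  expect_lt(max(abs(second_diff)), 1e-10)
})

test_that("untrimmed fit equals the exact constrained WLS oracle", {
  for (seed in c(29, 83, 97)) {
    sim <- default_sim(seed = seed, n_studies = 10)
    fit <- fit_signal(sim$table, trim_fraction = 0)
    A <- fit$design
    y <- fit$data$log_rr
    w <- 1 / fit$data$se_log_rr^2
    oracle <- constrained_wls_oracle(A, y, w)
    obj <- function(v) sum(w * (y - drop(A %*% v))^2)
    expect_equal(obj(fit$coefficients), oracle$value, tolerance = 1e-8)
    expect_equal(fit$coefficients, oracle$par, tolerance = 1e-6)
  }
})

test_that("trimming never increases the kept-set objective", {
  withr::with_seed(37, {
    for (r in 1:5) {
      sim <- default_sim(seed = 400 + r, n_studies = 15)
      tb <- sim$table
      # contaminate a few points to force trimming iterations; a common
      # multiplicative shift preserves the CI bracketing
      idx <- sample(nrow(tb), 3)
      shift <- exp(runif(3, 0.5, 1))
      tb$effect[idx] <- tb$effect[idx] * shift
      tb$ci_lower[idx] <- tb$ci_lower[idx] * shift
      tb$ci_upper[idx] <- tb$ci_upper[idx] * shift
      full <- fit_signal(tb, trim_fraction = 0)
      trimmed <- fit_signal(tb, trim_fraction = 0.10)
      w <- 1 / trimmed$data$se_log_rr^2
      kept <- trimmed$trim_mask
      # the trimmed solution beats the untrimmed one on its own kept set
      res_full <- trimmed$data$log_rr - full$fitted_signal
      expect_lte(trimmed$objective, sum(w[kept] * res_full[kept]^2) + 1e-10)
    }
  })
})

test_that("sample-size preconditions are enforced", {
  tb <- make_midpoint_table(c(50, 150, 250, 350))
  spec <- spline_spec(c(100, 200), domain = c(0, 400))
  expect_error(fit_signal(tb[1:2, ], spec), "at least")
  expect_error(fit_signal(tb, spec, trim_fraction = 0.6), "trim_fraction")
})
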
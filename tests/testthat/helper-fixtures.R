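# Build a valid study table from alternative-interval midpoints: one study,
# reference [0, ref_width], categories of width 2*half centred on each
# midpoint. Effects default to null with a fixed SE.
make_midpoint_table <- function(midpoints, half = 10, ref_width = 20,
                                log_rr = 0, se = 0.1,
                                study_id = "study_01") {
  n <- length(midpoints)
  log_rr <- rep_len(log_rr, n)
  se <- rep_len(se, n)
  tibble::tibble(
    study_id = rep_len(study_id, n),
    outcome = "fixture_outcome",
    ref_lower = 0, ref_upper = ref_width,
    alt_lower = midpoints - half, alt_upper = midpoints + half,
    measure_type = "RR",
    effect = exp(log_rr),
    ci_lower = exp(log_rr - qnorm(0.975) * se),
    ci_upper = exp(log_rr + qnorm(0.975) * se),
    sample_size = 10000, events = NA_real_, followup_years = 10
  )
}

# Table whose log effects follow a linear curve f(x) = slope * x exactly
# (interval averages of a linear function are midpoint values).
make_linear_table <- function(slope = -5e-4, midpoints = seq(50, 350, by = 50),
                              se = 0.05, ref_width = 20, half = 10) {
  avg <- function(lo, hi) slope * (lo + hi) / 2
  y <- avg(midpoints - half, midpoints + half) - avg(0, ref_width)
  tb <- make_midpoint_table(midpoints, half, ref_width, log_rr = y, se = se)
  # two study ids so heterogeneity is estimable downstream
  tb$study_id <- rep(c("study_01", "study_02"), length.out = nrow(tb))
  tb
}

# A deterministic synthetic dataset for smoke tests
default_sim <- function(seed = 11, n_studies = 20, ...) {
  simulate_study_table(sim_config(n_studies = n_studies, seed = seed, ...))
}

# internal spline curve constructors (exercised via package internals)
curve_linear <- function(slope, x_max = 400) {
  bopmeta:::.curve_new(2, c(0, x_max / 3, 2 * x_max / 3, x_max),
    rep(slope, 4)
  )
}

random_quadratic_curve <- function(x_max = 400) {
  knots <- sort(runif(2, 0.15 * x_max, 0.85 * x_max))
  bopmeta:::.curve_new(2, c(0, knots, x_max), -runif(4, 0, 0.01))
}

# closed-form weighted least squares for r ~ sd with weights w (Egger oracle)
wls_slope_oracle <- function(r, s, w) {
  xb <- sum(w * s) / sum(w)
  yb <- sum(w * r) / sum(w)
  sum(w * (s - xb) * (r - yb)) / sum(w * (s - xb)^2)
}

# exact oracle for sign-constrained WLS (v <= 0): enumerate active sets,
# solve the unconstrained WLS on the free coordinates, keep the best
# feasible solution
constrained_wls_oracle <- function(A, y, w) {
  p <- ncol(A)
  sw <- sqrt(w)
  Aw <- A * sw
  yw <- y * sw
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^p - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) == 0)
    v <- numeric(p)
    if (length(free)) {
      sol <- tryCatch(qr.coef(qr(Aw[, free, drop = FALSE]), yw),
        error = function(e) NULL
      )
      if (is.null(sol) || any(is.na(sol))) next
      v[free] <- sol
    }
    if (any(v > 1e-12)) next
    obj <- sum((yw - drop(Aw %*% v))^2)
    if (obj < best_obj) {
      best_obj <- obj
      best <- v
    }
  }
  list(par = best, value = best_obj)
}
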
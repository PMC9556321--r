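#' Fit the shape-constrained log-RR signal curve by trimmed weighted least
#' squares
#'
#' Minimises the inverse-variance-weighted residual sum of squares of the
#' observed log effect sizes against the interval-difference signal implied
#' by the spline, subject to the anchor f(0) = 0, a non-increasing shape,
#' and a linear right tail (all exact under the derivative parameterisation;
#' see [spline_spec()]). Robustness to incoherent observations follows a
#' trimmed-likelihood scheme: the `floor(trim_fraction * n)` observations
#' with the largest standardized residuals are excluded and the curve refit,
#' iterating until the excluded set stabilises (at most 20 iterations). Ties
#' in standardized residuals are broken by input order, so the fit is
#' deterministic given the table order.
#'
#' @param table A study table (see [as_study_table()]).
#' @param spec A [spline_spec()]; by default quadratic with two interior
#'   knots from [default_knots()] and domain up to the largest observed
#'   interval bound.
#' @param trim_fraction Proportion of observations to trim, in `[0, 0.5)`.
#'   Default 0.10.
#' @return An object of class `bop_signal_fit` with elements `spec`,
#'   `curve`, `coefficients` (free derivative values), `trim_mask` (TRUE =
#'   kept), `objective` (trimmed weighted RSS), `fitted_signal`, `iterations`,
#'   `converged`, and `data`.
#' @export
fit_signal <- function(table, spec = NULL, trim_fraction = 0.10) {
  table <- as_study_table(table)
  if (!is.numeric(trim_fraction) || trim_fraction < 0 || trim_fraction >= 0.5) {
    abort("`trim_fraction` must lie in [0, 0.5).")
  }
  if (is.null(spec)) {
    x_max <- max(table$alt_upper, table$ref_upper)
    spec <- spline_spec(
      interior_knots = default_knots(table),
      domain = c(0, x_max)
    )
  }
  if (!inherits(spec, "bop_spline_spec")) {
    abort("`spec` must be created by `spline_spec()`.")
  }
  n <- nrow(table)
  nfree <- .spec_nfree(spec)
  if (n < nfree) {
    abort(paste0(
      "Need at least ", nfree, " observations to fit ", nfree,
      " spline coefficients; got ", n, "."
    ))
  }

  # design: s_i is linear in the free derivative coefficients
  A <- vapply(seq_len(nfree), function(j) {
    v <- numeric(nfree)
    v[j] <- 1
    predict_signal(.spec_curve(spec, v), table)
  }, numeric(n))
  A <- matrix(A, nrow = n)
  y <- table$log_rr
  w <- 1 / table$se_log_rr^2

  n_trim <- floor(trim_fraction * n)
  keep <- rep(TRUE, n)
  v <- NULL
  iterations <- 0L
  converged <- TRUE
  repeat {
    iterations <- iterations + 1L
    v <- .solve_signal_wls(A[keep, , drop = FALSE], y[keep], w[keep], spec)
    if (n_trim == 0) break
    std_res <- abs(y - drop(A %*% v)) * sqrt(w)
    drop_idx <- order(-std_res, seq_len(n))[seq_len(n_trim)]
    new_keep <- rep(TRUE, n)
    new_keep[drop_idx] <- FALSE
    if (identical(new_keep, keep)) break
    if (iterations >= 20L) {
      warn("Trimming did not converge in 20 iterations; using last stable mask.")
      converged <- FALSE
      break
    }
    keep <- new_keep
  }

  curve <- .spec_curve(spec, v)
  fitted <- drop(A %*% v)
  objective <- sum(w[keep] * (y[keep] - fitted[keep])^2)
  structure(
    list(
      spec = spec, curve = curve, coefficients = v,
      trim_mask = keep, trim_fraction = trim_fraction,
      objective = objective, fitted_signal = fitted,
      iterations = iterations, converged = converged,
      design = A, data = table
    ),
    class = "bop_signal_fit"
  )
}

# weighted least squares with optional non-positivity of the derivative
# coefficients; the monotone case is a non-negative least-squares problem in
# the sign-flipped coefficients, solved exactly by Lawson-Hanson.
.solve_signal_wls <- function(A, y, w, spec) {
  sw <- sqrt(w)
  Aw <- A * sw
  yw <- y * sw
  if (spec$monotone_decreasing) {
    u <- pracma::lsqnonneg(-Aw, yw)$x
    -u
  } else {
    qr.coef(qr(Aw), yw)
  }
}

#' @export
print.bop_signal_fit <- function(x, ...) {
  cat("Shape-constrained log-RR signal curve\n")
  cat(
    "  degree ", x$spec$degree, ", interior knots at ",
    paste(signif(x$spec$interior_knots, 5), collapse = ", "),
    " g/day, domain [0, ", x$spec$domain[2], "]\n",
    sep = ""
  )
  cat(
    "  n = ", length(x$trim_mask), " observations (",
    sum(!x$trim_mask), " trimmed), objective = ",
    signif(x$objective, 6), "\n",
    sep = ""
  )
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.bop_signal_fit <- function(x, ...) {
  breaks <- x$curve$breaks
  if (x$spec$degree == 2) {
    tibble::tibble(
      term = paste0("dfdx@", signif(breaks, 6)),
      exposure = breaks, estimate = x$curve$dvals
    )
  } else {
    tibble::tibble(
      term = paste0("slope[", signif(breaks[-length(breaks)], 6), ",",
        signif(breaks[-1], 6), "]"
      ),
      exposure = breaks[-length(breaks)], estimate = x$curve$dvals
    )
  }
}

#' @exportS3Method generics::glance
glance.bop_signal_fit <- function(x, ...) {
  tibble::tibble(
    n = length(x$trim_mask),
    n_trimmed = sum(!x$trim_mask),
    objective = x$objective,
    iterations = x$iterations,
    converged = x$converged
  )
}
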
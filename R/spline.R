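#' Specify the shape-constrained spline for the log-RR signal curve
#'
#' The exposure-response signal f(x) is a quadratic spline on `domain`
#' (g/day), anchored at f(0) = 0 so the curve reads as log relative risk
#' versus zero exposure. Default priors match the protective-risk
#' configuration: a monotonic decreasing constraint and a linearity
#' constraint (zero curvature) to the right of the last interior knot.
#'
#' Internally the spline is parameterised by the values of its derivative at
#' the knot vector. For a quadratic spline the derivative is continuous and
#' piecewise linear, so the anchor, the linear tail, and monotonicity
#' (derivative values <= 0) are all exact by construction rather than
#' enforced approximately on a grid.
#'
#' @param interior_knots Strictly increasing exposures strictly inside
#'   `domain`.
#' @param domain Length-2 numeric, `c(0, x_max)` g/day.
#' @param degree Polynomial degree, 1 or 2 (default 2).
#' @param monotone_decreasing Constrain f to be non-increasing.
#' @param linear_right_tail Constrain f to be linear right of the last
#'   interior knot (degree 2 only).
#' @return An object of class `bop_spline_spec`.
#' @export
spline_spec <- function(interior_knots, domain = c(0, max(interior_knots) * 2),
                        degree = 2, monotone_decreasing = TRUE,
                        linear_right_tail = TRUE) {
  if (!degree %in% c(1, 2)) abort("`degree` must be 1 or 2.")
  if (length(domain) != 2 || domain[1] != 0 || domain[2] <= 0) {
    abort("`domain` must be c(0, x_max) with x_max > 0.")
  }
  k <- as.numeric(interior_knots)
  if (length(k) < 1 || any(!is.finite(k)) || any(diff(k) <= 0) ||
      k[1] <= domain[1] || k[length(k)] >= domain[2]) {
    abort("`interior_knots` must be strictly increasing and strictly inside `domain`.")
  }
  structure(
    list(
      degree = degree, interior_knots = k, domain = domain,
      monotone_decreasing = isTRUE(monotone_decreasing),
      linear_right_tail = isTRUE(linear_right_tail)
    ),
    class = "bop_spline_spec"
  )
}

#' Default interior knot placement
#'
#' Places the two interior knots at the 33 1/3rd and 66 2/3rd percentiles of
#' the alternative-interval midpoints (linear-interpolation percentile
#' convention, rank `p * (n - 1) + 1`), a deterministic simplification of
#' ensemble knot selection.
#'
#' @param table A study table.
#' @return Numeric vector of two interior knots (g/day).
#' @export
default_knots <- function(table) {
  table <- as_study_table(table)
  mids <- (table$alt_lower + table$alt_upper) / 2
  if (length(unique(mids)) < 4) {
    abort("Need at least 4 distinct alternative-interval midpoints to place knots.")
  }
  unname(quantile(mids, c(1, 2) / 3, type = 7))
}

# ---- internal curve representation -----------------------------------------
# A curve is a list(degree, breaks, dvals):
#   breaks: c(0, interior knots, x_max)
#   dvals : derivative values; degree 2 -> at each break (length B),
#           degree 1 -> constant per segment (length B - 1).
# Curve values at breaks and cumulative integrals are precomputed lazily.

.curve_new <- function(degree, breaks, dvals) {
  B <- length(breaks)
  h <- diff(breaks)
  if (degree == 2) {
    stopifnot(length(dvals) == B)
    dl <- dvals[-B]
    dr <- dvals[-1]
    fvals <- c(0, cumsum(h * (dl + dr) / 2))
    # segment integrals of f: F_m h + dl h^2/2 + (dr - dl) h^2/6
    seg_int <- fvals[-B] * h + dl * h^2 / 2 + (dr - dl) * h^2 / 6
  } else {
    stopifnot(length(dvals) == B - 1)
    fvals <- c(0, cumsum(h * dvals))
    seg_int <- fvals[-B] * h + dvals * h^2 / 2
  }
  list(
    degree = degree, breaks = breaks, dvals = dvals,
    fvals = fvals, cumint = c(0, cumsum(seg_int))
  )
}

.curve_seg <- function(curve, x) {
  # segment index such that breaks[i] <= x <= breaks[i+1]
  i <- findInterval(x, curve$breaks, rightmost.closed = TRUE)
  pmin(pmax(i, 1L), length(curve$breaks) - 1L)
}

.curve_eval <- function(curve, x) {
  b <- curve$breaks
  out_of <- x < b[1] - 1e-9 | x > b[length(b)] + 1e-9
  if (any(out_of)) {
    abort(paste0(
      "Exposure ", signif(x[which(out_of)[1]], 6),
      " g/day is outside the curve domain [", b[1], ", ", b[length(b)], "]."
    ))
  }
  i <- .curve_seg(curve, x)
  t <- x - b[i]
  h <- b[i + 1] - b[i]
  if (curve$degree == 2) {
    dl <- curve$dvals[i]
    dd <- curve$dvals[i + 1] - dl
    curve$fvals[i] + dl * t + dd * t^2 / (2 * h)
  } else {
    curve$fvals[i] + curve$dvals[i] * t
  }
}

# exact integral of f over [0, x]
.curve_cumint <- function(curve, x) {
  b <- curve$breaks
  i <- .curve_seg(curve, x)
  t <- x - b[i]
  h <- b[i + 1] - b[i]
  Fm <- curve$fvals[i]
  if (curve$degree == 2) {
    dl <- curve$dvals[i]
    dd <- curve$dvals[i + 1] - dl
    curve$cumint[i] + Fm * t + dl * t^2 / 2 + dd * t^3 / (6 * h)
  } else {
    curve$cumint[i] + Fm * t + curve$dvals[i] * t^2 / 2
  }
}

.spec_breaks <- function(spec) {
  c(spec$domain[1], spec$interior_knots, spec$domain[2])
}

# number of free derivative coefficients and the dvals expansion
.spec_nfree <- function(spec) {
  B <- length(.spec_breaks(spec))
  if (spec$degree == 1) {
    B - 1L
  } else if (spec$linear_right_tail) {
    B - 1L
  } else {
    B
  }
}

.spec_expand <- function(spec, v) {
  B <- length(.spec_breaks(spec))
  if (spec$degree == 1) {
    v
  } else if (spec$linear_right_tail) {
    c(v, v[length(v)])
  } else {
    v
  }
}

.spec_curve <- function(spec, v) {
  .curve_new(spec$degree, .spec_breaks(spec), .spec_expand(spec, v))
}

# ---- public curve operations -----------------------------------------------

.as_curve <- function(object) {
  if (inherits(object, "bop_signal_fit")) {
    object$curve
  } else if (is.list(object) && !is.null(object$breaks)) {
    object
  } else {
    abort("Expected a `bop_signal_fit` or an internal curve object.")
  }
}

#' Average of the signal curve over an exposure interval
#'
#' Computes `(1 / (b - a)) * integral_a^b f(x) dx` by exact
#' piecewise-polynomial integration. Extracted observations compare exposure
#' categories spanning ranges, so the model maps intervals (not points) onto
#' the curve.
#'
#' @param fit A [fit_signal()] result.
#' @param interval Length-2 numeric (lower, upper) g/day inside the curve
#'   domain.
#' @return The interval-averaged log RR (scalar).
#' @export
interval_average <- function(fit, interval) {
  curve <- .as_curve(fit)
  a <- interval[1]
  b <- interval[2]
  dom <- range(curve$breaks)
  if (!all(is.finite(c(a, b))) || a < dom[1] - 1e-9 || b > dom[2] + 1e-9) {
    abort(paste0(
      "Interval [", a, ", ", b, "] lies outside the curve domain [",
      dom[1], ", ", dom[2], "]."
    ))
  }
  if (a == b) return(.curve_eval(curve, a))
  (.curve_cumint(curve, b) - .curve_cumint(curve, a)) / (b - a)
}

#' Predicted signal for alternative-vs-reference comparisons
#'
#' For each observation the signal is the interval-averaged curve value over
#' the alternative exposure interval minus that over the reference interval.
#'
#' @param fit A [fit_signal()] result.
#' @param table A study table (or any data frame with `ref_lower`,
#'   `ref_upper`, `alt_lower`, `alt_upper` columns).
#' @return Numeric vector of signals, one per row.
#' @export
predict_signal <- function(fit, table) {
  curve <- .as_curve(fit)
  purrr::map_dbl(seq_len(nrow(table)), function(i) {
    interval_average(curve, c(table$alt_lower[i], table$alt_upper[i])) -
      interval_average(curve, c(table$ref_lower[i], table$ref_upper[i]))
  })
}

#' Evaluate the fitted signal curve on a grid
#'
#' @param fit A [fit_signal()] result.
#' @param n Number of grid points, or supply `exposure` directly.
#' @param exposure Optional explicit exposure grid (g/day).
#' @return A tibble with columns `exposure`, `log_rr`.
#' @export
signal_grid <- function(fit, n = 200, exposure = NULL) {
  curve <- .as_curve(fit)
  if (is.null(exposure)) {
    exposure <- seq(curve$breaks[1], curve$breaks[length(curve$breaks)],
      length.out = n
    )
  }
  tibble::tibble(exposure = exposure, log_rr = .curve_eval(curve, exposure))
}
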
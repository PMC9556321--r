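#' Standardize a reported exposure category to a closed interval in g/day
#'
#' Extracted consumption categories arrive in heterogeneous shapes: gram
#' ranges, serving ranges, and open-ended bounds. Standardization applies, in
#' order: (1) servings are converted to grams at `serving_size_g`
#' (defaulting to 77 g per serving when the study defines none); (2) an
#' undefined lower bound becomes 0 g/day; (3) an undefined upper bound is
#' closed by adding the width of the study's adjacent (next lower) closed
#' category. Categories reported only as per-category means are handled at
#' the ladder level by [intervals_from_means()].
#'
#' @param raw_category Character scalar or vector, e.g. `"100-200 g/day"`,
#'   `"2-4 servings/day"`, `"<100 g/day"`, `">300 g/day"`.
#' @param serving_size_g Grams per serving used when the category is
#'   expressed in servings; `NULL` uses the 77 g default.
#' @param adjacent_interval Optional length-2 numeric (lower, upper) g/day:
#'   the study's most adjacent closed category, used to close an open upper
#'   bound.
#' @return A tibble with columns `lower` and `upper` (g/day), one row per
#'   category.
#' @examples
#' standardize_exposure("2-4 servings/day")
#' standardize_exposure("<100 g/day")
#' standardize_exposure(">300 g/day", adjacent_interval = c(200, 300))
#' @export
standardize_exposure <- function(raw_category, serving_size_g = NULL,
                                 adjacent_interval = NULL) {
  serving_size_g <- serving_size_g %||% 77
  if (!is.numeric(serving_size_g) || serving_size_g <= 0) {
    abort("`serving_size_g` must be a positive number.")
  }
  if (!is.null(adjacent_interval)) {
    if (length(adjacent_interval) != 2 ||
        !all(is.finite(adjacent_interval)) ||
        adjacent_interval[1] >= adjacent_interval[2]) {
      abort("`adjacent_interval` must be a finite (lower, upper) pair.")
    }
  }
  rows <- purrr::map(raw_category, .standardize_one,
    serving_size_g = serving_size_g, adjacent_interval = adjacent_interval
  )
  dplyr::bind_rows(rows)
}

.standardize_one <- function(category, serving_size_g, adjacent_interval) {
  x <- trimws(as.character(category))
  if (!nzchar(x)) abort("Empty exposure category.")
  in_servings <- grepl("serv", x, ignore.case = TRUE)
  unit <- if (in_servings) serving_size_g else 1
  num <- "([0-9]*\\.?[0-9]+)"
  grab <- function(pattern) {
    m <- regmatches(x, regexec(pattern, x))[[1]]
    if (length(m)) as.numeric(m[-1]) else NULL
  }
  rng <- grab(paste0(num, "\\s*(?:-|–|−|to)\\s*", num))
  lt <- grab(paste0("^\\s*(?:<|≤)\\s*", num))
  gt <- grab(paste0("^\\s*(?:>|≥)\\s*", num))
  if (is.null(gt)) gt <- grab(paste0("^\\s*", num, "\\s*\\+"))

  if (!is.null(rng)) {
    lower <- rng[1] * unit
    upper <- rng[2] * unit
  } else if (!is.null(lt)) {
    lower <- 0
    upper <- lt[1] * unit
  } else if (!is.null(gt)) {
    lower <- gt[1] * unit
    if (is.null(adjacent_interval)) {
      abort(paste0(
        "Cannot resolve open upper bound of category \"", category,
        "\": supply `adjacent_interval` (or per-category means)."
      ))
    }
    upper <- lower + diff(adjacent_interval)
  } else {
    abort(paste0("Unrecognised exposure category: \"", category, "\"."))
  }
  if (lower >= upper) {
    abort(paste0("Degenerate interval from category \"", category, "\"."))
  }
  tibble::tibble(lower = lower, upper = upper)
}

#' Intervals for a fully means-based category ladder
#'
#' When a study reports only mean consumption per category, interval cutoffs
#' are placed at the midpoints between adjacent means. The lowest category's
#' lower bound is 0 g/day; the highest category's upper bound extends the
#' top mean symmetrically beyond the last cutoff.
#'
#' @param means Strictly increasing numeric vector of per-category mean
#'   consumption (g/day), length >= 2.
#' @return A tibble with columns `lower`, `upper`, one row per category.
#' @examples
#' intervals_from_means(c(20, 80, 200))
#' @export
intervals_from_means <- function(means) {
  if (length(means) < 2 || any(!is.finite(means)) || any(diff(means) <= 0)) {
    abort("`means` must be a strictly increasing numeric vector, length >= 2.")
  }
  cuts <- (head(means, -1) + tail(means, -1)) / 2
  n <- length(means)
  lower <- c(0, cuts)
  upper <- c(cuts, means[n] + (means[n] - cuts[n - 1]))
  tibble::tibble(lower = lower, upper = upper)
}
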
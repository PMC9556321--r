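#' Convert a reported relative measure and 95% CI to a log scale effect size
#'
#' Relative measures (RR, OR, HR) are modelled on the natural-log scale. The
#' standard error is recovered from the 95% confidence interval assuming the
#' interval is symmetric on the log scale:
#' `se = (log(ci_upper) - log(ci_lower)) / (2 * qnorm(0.975))`.
#'
#' @param point Point estimate of the relative measure (> 0).
#' @param ci_lower,ci_upper Bounds of the reported 95% CI, with
#'   `0 < ci_lower <= point <= ci_upper` and `ci_lower < ci_upper`.
#'
#' @return A tibble with one row per input and columns `log_rr`, `se_log_rr`.
#' @examples
#' parse_effect_size(0.84, 0.79, 0.90)
#' @export
parse_effect_size <- function(point, ci_lower, ci_upper) {
  n <- length(point)
  if (length(ci_lower) != n || length(ci_upper) != n) {
    abort("`point`, `ci_lower`, and `ci_upper` must have equal length.")
  }
  bad <- !is.finite(point) | !is.finite(ci_lower) | !is.finite(ci_upper) |
    point <= 0 | ci_lower <= 0 | ci_upper <= 0
  if (any(bad)) {
    abort(paste0(
      "Relative measures and CI bounds must be positive and finite ",
      "(offending element ", which(bad)[1], ")."
    ))
  }
  if (any(ci_upper == ci_lower)) {
    abort("Zero-width confidence interval: `ci_lower` equals `ci_upper`.")
  }
  disordered <- ci_lower > point | point > ci_upper
  if (any(disordered)) {
    abort(paste0(
      "CI must bracket the point estimate: violated at element ",
      which(disordered)[1], "."
    ))
  }
  tibble::tibble(
    log_rr = log(point),
    se_log_rr = (log(ci_upper) - log(ci_lower)) / (2 * Z975)
  )
}

# mandatory columns of the study-table schema, in canonical order
.study_cols <- c(
  "study_id", "outcome", "ref_lower", "ref_upper", "alt_lower", "alt_upper",
  "measure_type", "effect", "ci_lower", "ci_upper", "sample_size", "events",
  "followup_years"
)

#' Validate a study table and derive log-scale effect sizes
#'
#' A study table holds one exposure comparison per row: a reference interval
#' and an alternative interval (g/day), the reported relative measure with its
#' 95% CI, and zero or more `cv_*` binary study-design covariates. This
#' function checks the schema and invariants and appends `log_rr` and
#' `se_log_rr` columns derived by [parse_effect_size()].
#'
#' @param data A data frame following the study-table schema (see
#'   [read_study_table()]).
#' @return A validated tibble with `log_rr` and `se_log_rr` columns.
#' @export
as_study_table <- function(data) {
  data <- tibble::as_tibble(data)
  missing_cols <- setdiff(.study_cols, names(data))
  if (length(missing_cols)) {
    abort(paste0(
      "Missing mandatory study-table column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  if (nrow(data) == 0) abort("Study table must contain at least one record.")
  if (length(unique(data$outcome)) > 1) {
    abort("All records in a study table must share one outcome.")
  }
  num_cols <- c(
    "ref_lower", "ref_upper", "alt_lower", "alt_upper",
    "effect", "ci_lower", "ci_upper"
  )
  for (cl in num_cols) {
    if (!is.numeric(data[[cl]])) {
      abort(paste0("Column `", cl, "` must be numeric."))
    }
  }
  check_interval <- function(lo, hi, what) {
    bad <- !is.finite(lo) | !is.finite(hi) | lo < 0 | lo >= hi
    if (any(bad)) {
      abort(paste0(
        "Invalid ", what, " exposure interval at row ", which(bad)[1],
        ": need 0 <= lower < upper, both finite."
      ))
    }
  }
  check_interval(data$ref_lower, data$ref_upper, "reference")
  check_interval(data$alt_lower, data$alt_upper, "alternative")
  same <- data$ref_lower == data$alt_lower & data$ref_upper == data$alt_upper
  if (any(same)) {
    abort(paste0(
      "Alternative interval identical to reference at row ",
      which(same)[1], "."
    ))
  }
  bad_measure <- !data$measure_type %in% c("RR", "OR", "HR")
  if (any(bad_measure)) {
    abort(paste0(
      "`measure_type` must be one of RR, OR, HR (row ",
      which(bad_measure)[1], ")."
    ))
  }
  es <- tryCatch(
    parse_effect_size(data$effect, data$ci_lower, data$ci_upper),
    error = function(e) {
      abort(paste0("Invalid effect size / CI: ", conditionMessage(e)))
    }
  )
  cv <- covariate_names(data)
  for (cl in cv) {
    v <- data[[cl]]
    if (!is.numeric(v) || any(!is.finite(v)) ||
        any(v < 0) || any(v != round(v)) || any(v > 10)) {
      abort(paste0(
        "Covariate column `", cl, "` must hold small non-negative integers ",
        "(0/1 or a short ordinal scale)."
      ))
    }
  }
  out <- dplyr::mutate(data, log_rr = es$log_rr, se_log_rr = es$se_log_rr)
  if (length(unique(out$study_id)) < 2) {
    attr(out, "single_study") <- TRUE
  }
  out
}

#' Names of bias-covariate columns in a study table
#'
#' @param data A study table.
#' @return Character vector of `cv_*` column names (possibly empty).
#' @export
covariate_names <- function(data) {
  grep("^cv_", names(data), value = TRUE)
}

#' Read or write a study table
#'
#' The on-disk format is a UTF-8 CSV with one header row and one observation
#' per row. Mandatory columns: `study_id`, `outcome`, `ref_lower`,
#' `ref_upper`, `alt_lower`, `alt_upper` (exposures in g/day),
#' `measure_type` (RR/OR/HR), `effect`, `ci_lower`, `ci_upper`,
#' `sample_size`, `events`, `followup_years`; plus optional `cv_<name>`
#' 0/1 covariate columns. Reading validates every row; malformed rows are
#' reported with their (1-based, header-inclusive) line numbers.
#'
#' @param path Path to a CSV file.
#' @return `read_study_table()` returns a validated study-table tibble.
#' @export
read_study_table <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(.study_cols, names(raw))
  if (length(missing_cols)) {
    abort(paste0(
      "File ", path, " is missing mandatory column(s): ",
      paste(missing_cols, collapse = ", "), "."
    ))
  }
  for (cl in c("ref_lower", "ref_upper", "alt_lower", "alt_upper",
               "effect", "ci_lower", "ci_upper")) {
    if (!is.numeric(raw[[cl]])) {
      first_bad <- which(is.na(suppressWarnings(as.numeric(raw[[cl]]))))[1]
      abort(paste0(
        "Non-numeric value in column `", cl, "` of ", path,
        " (data line ", first_bad + 1, ")."
      ))
    }
  }
  # validate row by row so errors carry file line numbers (header is line 1)
  for (i in seq_len(nrow(raw))) {
    tryCatch(
      as_study_table(raw[i, , drop = FALSE]),
      error = function(e) {
        abort(paste0(
          "Malformed row at line ", i + 1, " of ", path, ": ",
          conditionMessage(e)
        ))
      }
    )
  }
  as_study_table(raw)
}

#' @rdname read_study_table
#' @param table A study table (see [as_study_table()]).
#' @return `write_study_table()` invisibly returns `path`.
#' @export
write_study_table <- function(table, path) {
  table <- as_study_table(table)
  out <- dplyr::select(
    table,
    dplyr::all_of(.study_cols), dplyr::starts_with("cv_")
  )
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
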
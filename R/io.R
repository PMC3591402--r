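#' Read and validate cohort CSV files
#'
#' `read_amh_csv` expects the header
#' `subject_id,age_years,amh_ng_ml,bmi,smoker` (smoker coded 0/1);
#' `read_menopause_csv` expects
#' `subject_id,age_menopause_years,bmi_category,smoker` with `bmi_category`
#' in `c("under", "normal", "over", "obese")`. Row-level problems (missing
#' columns, non-numeric fields, out-of-range values) are aggregated and
#' reported together rather than one at a time. A header-only file yields an
#' empty tibble with a warning.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble.
#' @export
read_amh_csv <- function(path) {
  df <- read_cohort(path, cols = list(subject_id = "c", age_years = "d",
                                      amh_ng_ml = "d", bmi = "d", smoker = "i"))
  if (nrow(df) == 0) return(df)
  problems <- c(
    row_problems(df, !is.finite(df$age_years) | df$age_years <= 0,
                 "age_years must be positive"),
    row_problems(df, !is.finite(df$amh_ng_ml) | df$amh_ng_ml <= 0,
                 "amh_ng_ml must be positive (log is taken)"),
    row_problems(df, !is.finite(df$bmi) | df$bmi <= 10, "bmi must exceed 10"),
    row_problems(df, !df$smoker %in% c(0L, 1L), "smoker must be 0 or 1"))
  report_problems(problems, path)
  df
}

#' @rdname read_amh_csv
#' @export
read_menopause_csv <- function(path) {
  df <- read_cohort(path, cols = list(subject_id = "c",
                                      age_menopause_years = "d",
                                      bmi_category = "c", smoker = "i"))
  if (nrow(df) == 0) return(df)
  problems <- c(
    row_problems(df, !is.finite(df$age_menopause_years) |
                   df$age_menopause_years <= 35 | df$age_menopause_years >= 65,
                 "age_menopause_years must lie in (35, 65)"),
    row_problems(df, !df$bmi_category %in% bmi_levels,
                 paste("bmi_category must be one of:",
                       paste(bmi_levels, collapse = ", "))),
    row_problems(df, !df$smoker %in% c(0L, 1L), "smoker must be 0 or 1"))
  report_problems(problems, path)
  df
}

read_cohort <- function(path, cols) {
  if (!file.exists(path)) stop("file not found: ", path)
  spec <- do.call(readr::cols_only,
                  lapply(cols, function(k) switch(k,
                                                  c = readr::col_character(),
                                                  d = readr::col_double(),
                                                  i = readr::col_integer())))
  header <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE))
  missing_cols <- setdiff(names(cols), header)
  if (length(missing_cols)) {
    stop("file ", path, " is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  # readr warns about parse problems lazily; those problems are re-reported
  # below as an aggregated error, so the warning itself is redundant
  df <- suppressWarnings(readr::read_csv(path, col_types = spec,
                                         show_col_types = FALSE))
  pr <- readr::problems(df)
  if (nrow(pr)) {
    stop("file ", path, " has unparseable fields:\n",
         paste(sprintf("  row %d, column %s: expected %s, got '%s'",
                       pr$row, header[pr$col], pr$expected, pr$actual),
               collapse = "\n"))
  }
  if (nrow(df) == 0) warning("file ", path, " contains a header but no records")
  df
}

row_problems <- function(df, bad, msg) {
  idx <- which(bad)
  if (!length(idx)) return(character())
  sprintf("row %d: %s", idx, msg)
}

report_problems <- function(problems, path) {
  if (length(problems)) {
    stop("invalid records in ", path, ":\n",
         paste(utils::head(problems, 20), collapse = "\n"),
         if (length(problems) > 20) sprintf("\n  ... and %d more",
                                            length(problems) - 20) else "")
  }
}

#' Write tables of fitted results as CSV
#'
#' `write_centiles_csv` writes an [amh_centiles()] table in wide form (rows =
#' ages, one column per centile); `write_percentiles_csv` writes a
#' [meno_percentiles()] table in wide form (rows = profiles); and
#' `write_thresholds_csv` writes per-profile thresholds (BMI category by
#' smoking status). Numbers are written at full precision; any rounding is
#' for display only and never applied here.
#'
#' @param x The table to write.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_centiles_csv <- function(x, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x), names_from = "prob",
                             values_from = "amh_ng_ml", names_prefix = "p")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_centiles_csv
#' @export
write_percentiles_csv <- function(x, path) {
  wide <- tidyr::pivot_wider(tibble::as_tibble(x), names_from = "prob",
                             values_from = "age_years", names_prefix = "p")
  readr::write_csv(wide, path)
  invisible(path)
}

#' @rdname write_centiles_csv
#' @export
write_thresholds_csv <- function(x, path) {
  stopifnot(inherits(x, "threshold_fit") || inherits(x, "meno_model"))
  model <- resolve_meno_model(x)
  tab <- covariate_profiles()
  tab$threshold_ng_ml <- exp(model$log_thresholds[
    profile_key(tab$bmi_category, tab$smoker)])
  wide <- tidyr::pivot_wider(tab, names_from = "smoker",
                             values_from = "threshold_ng_ml",
                             names_prefix = "smoker_")
  readr::write_csv(wide, path)
  invisible(path)
}
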
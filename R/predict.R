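#' Predict a menopausal-age interval for individual women
#'
#' Two-stage individual prediction: the woman's `(age, AMH)` is first located
#' within the age-dependent AMH centile bands of the stage-1 regression; her
#' predicted age at menopause is then the interval between the matching
#' percentiles of the menopausal-age distribution for her BMI and smoking
#' profile. A measurement in the 25-50% AMH band, for instance, maps to the
#' interval between the 25th and 50th percentiles of menopausal age.
#'
#' The outer bands are open-ended: for a measurement below the 5th centile
#' the interval's lower edge is the 1st menopausal-age percentile and is
#' flagged as an extrapolation (`note = "lower edge extrapolated at p=0.01"`);
#' above the 95th centile the upper edge is unbounded (`age_high = Inf`).
#'
#' @param fit A `threshold_fit` (carries both model stages).
#' @param age Age in years (vectorized; a warning is issued outside the
#'   stage-1 validity range 25-45 y).
#' @param amh Serum AMH in ng/mL (positive).
#' @param smoker 0 (never) or 1 (current or past).
#' @param bmi Continuous BMI in kg/m^2 (classified with the standard
#'   cut-points), or supply `bmi_category` directly.
#' @param bmi_category One of `c("under", "normal", "over", "obese")`.
#' @return A tibble with one row per input: the inputs, `band_low`,
#'   `band_high`, `age_low`, `age_high` (years) and `note`.
#' @examples
#' cfg <- meno_config(seed = 1)
#' af <- fit_amh(simulate_amh_cohort(cfg))
#' tf <- fit_threshold(simulate_menopause_cohort(cfg), af)
#' predict_menopause(tf, age = 30, amh = 2.5, bmi = 22, smoker = 0)
#' @export
predict_menopause <- function(fit, age, amh, smoker, bmi = NULL,
                              bmi_category = NULL) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (is.null(bmi_category)) {
    if (is.null(bmi)) stop("supply either `bmi` or `bmi_category`")
    bmi_category <- classify_bmi(bmi)
  }
  n <- max(length(age), length(amh), length(smoker), length(bmi_category))
  age <- rep_len(age, n); amh <- rep_len(amh, n)
  smoker <- rep_len(smoker, n); bmi_category <- rep_len(bmi_category, n)
  band <- amh_band(fit$amh_fit, age, amh)
  model <- fit$model
  lo_support <- model$peak_age + 0.5
  # percentile with a guarded fallback for the extrapolated 1% edge: on
  # heavy-tailed fits the threshold-crossing probability at the support edge
  # can already exceed 1%
  pct <- function(cat, sm, p, extrapolated = FALSE) {
    f <- function(y) meno_cdf(model, y, cat, sm) - p
    if (f(lo_support) > 0) {
      if (extrapolated) return(lo_support)
      stop(sprintf("percentile %g below model support for profile %s",
                   p, profile_key(cat, sm)))
    }
    stats::uniroot(f, c(lo_support, 80), tol = 1e-10)$root
  }
  out <- purrr::pmap(
    list(band$band_low, band$band_high, bmi_category, smoker),
    function(lo, hi, cat, sm) {
      if (lo == 0) {
        list(age_low = pct(cat, sm, 0.01, extrapolated = TRUE),
             age_high = pct(cat, sm, 0.05),
             note = "lower edge extrapolated at p=0.01")
      } else if (hi == 1) {
        list(age_low = pct(cat, sm, 0.95), age_high = Inf,
             note = "upper edge unbounded (above 95th centile)")
      } else {
        list(age_low = pct(cat, sm, lo), age_high = pct(cat, sm, hi),
             note = "")
      }
    })
  tibble::tibble(age_years = age, amh_ng_ml = amh,
                 bmi_category = bmi_category, smoker = as.integer(smoker),
                 band_low = band$band_low, band_high = band$band_high,
                 age_low = purrr::map_dbl(out, "age_low"),
                 age_high = purrr::map_dbl(out, "age_high"),
                 note = purrr::map_chr(out, "note"))
}

#' Machine-readable prediction report
#'
#' Packages a set of predictions with the provenance needed to reproduce
#' them: a hash of the two fitted parameter sets, the package version, and
#' the model summaries. Identical inputs produce identical reports, and the
#' report round-trips through JSON unchanged.
#'
#' @param predictions Output of [predict_menopause()].
#' @param fit The `threshold_fit` used.
#' @return A list of class `meno_report` with elements `predictions`,
#'   `model_hash`, `parameters`, `package_version`.
#' @export
prediction_report <- function(predictions, fit) {
  stopifnot(inherits(fit, "threshold_fit"))
  params <- list(
    stage1 = list(coefficients = as.list(fit$amh_fit$coefficients),
                  residual_scale = fit$amh_fit$residual$scale,
                  shape_a = fit$amh_fit$residual$a,
                  shape_b = fit$amh_fit$residual$b),
    stage2 = list(alpha = fit$alpha, beta_bmi = as.list(fit$beta_bmi),
                  gamma_smoke = fit$gamma_smoke, kappa = fit$kappa))
  structure(list(predictions = as.data.frame(predictions),
                 model_hash = rlang::hash(params),
                 parameters = params,
                 package_version = as.character(utils::packageVersion("menothresh"))),
            class = "meno_report")
}

#' Serialize and restore a prediction report
#'
#' @param report A `meno_report`.
#' @param path File path for the JSON document.
#' @return `write_report` invisibly returns `path`; `read_report` returns
#'   the restored `meno_report`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "meno_report"))
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$predictions <- as.data.frame(raw$predictions)
  structure(raw, class = "meno_report")
}
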
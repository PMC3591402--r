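#' Serialize and restore a generator configuration
#'
#' The configuration is written as a versioned JSON document carrying every
#' generative parameter and the seed, so a pipeline run can be reproduced
#' exactly from its config echo.
#'
#' @param cfg A [meno_config()].
#' @param path JSON file path.
#' @return `write_config` invisibly returns `path`; `read_config` returns a
#'   `meno_config`.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "meno_config"))
  doc <- c(list(schema = "menothresh-config", schema_version = 1L),
           unclass(cfg))
  # named numeric vectors are stored as JSON objects (plain arrays would drop
  # the names); 17 significant digits make the double roundtrip exact
  doc$thresholds <- as.list(doc$thresholds)
  doc$bmi_category_probs <- as.list(doc$bmi_category_probs)
  doc$calibration$coefs <- as.list(doc$calibration$coefs)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$schema, "menothresh-config")) {
    stop("file ", path, " is not a menothresh configuration (schema field missing)")
  }
  cal <- doc$calibration
  cal$coefs <- unlist(cal$coefs)
  meno_config(seed = doc$seed, n_amh = doc$n_amh, n_meno = doc$n_meno,
              age_range = unlist(doc$age_range), bmi_mean = doc$bmi_mean,
              bmi_sd = doc$bmi_sd, smoke_prob_amh = doc$smoke_prob_amh,
              smoke_prob_meno = doc$smoke_prob_meno,
              bmi_category_probs = unlist(doc$bmi_category_probs),
              thresholds = unlist(doc$thresholds),
              calibration = cal)
}

#' Run the full two-stage pipeline
#'
#' Simulates the paired cohorts, fits both model stages, and writes every
#' artifact to `out_dir`: the cohort CSVs, fitted parameters (JSON), AMH
#' centile and menopausal-age percentile tables (CSV, full precision), the
#' per-profile threshold table, a no-covariate percentile table, example
#' predictions, and a manifest recording the config, seeds, per-stage
#' log-likelihoods, convergence, file digests and package version. Two runs
#' from the same config produce byte-identical tables.
#'
#' @param config A [meno_config()] or the path to a config JSON.
#' @param out_dir Output directory (created if needed).
#' @param predict_inputs Optional tibble with `age_years`, `amh_ng_ml`,
#'   `bmi`, `smoker` for batch prediction; defaults to a single illustrative
#'   measurement (age 30, AMH 2.5 ng/mL, BMI 22, non-smoker).
#' @param quiet Suppress progress messages.
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir, predict_inputs = NULL,
                         quiet = FALSE) {
  cfg <- if (is.character(config)) read_config(config) else config
  stopifnot(inherits(cfg, "meno_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  p <- function(f) file.path(out_dir, f)

  say("simulate: seed %d (AMH cohort), %d (menopause cohort)",
      cfg$seed, cfg$seed + 1L)
  amh <- simulate_amh_cohort(cfg)
  meno <- simulate_menopause_cohort(cfg)
  readr::write_csv(amh, p("amh_cohort.csv"))
  readr::write_csv(meno, p("menopause_cohort.csv"))
  write_config(cfg, p("config_echo.json"))

  af <- fit_amh(amh)
  say("fit-amh: loglik %.3f, converged %s, peak age %.2f",
      af$loglik, af$converged, peak_age(af))
  tf <- fit_threshold(meno, af)
  say("fit-threshold: loglik %.3f, converged %s, kappa %.3f",
      tf$loglik, tf$converged, tf$kappa)
  tf0 <- fit_threshold(meno, af, covariates = FALSE)
  say("fit-threshold (no covariates): loglik %.3f", tf0$loglik)

  params <- list(stage1 = as.list(tidy(af) |> tibble::deframe()),
                 stage2 = as.list(tidy(tf) |> tibble::deframe()),
                 stage2_no_covariates = list(alpha = tf0$alpha,
                                             kappa = tf0$kappa))
  jsonlite::write_json(params, p("fitted_params.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  write_centiles_csv(amh_centiles(af), p("amh_centiles.csv"))
  write_thresholds_csv(tf, p("thresholds.csv"))
  write_percentiles_csv(meno_percentiles(tf), p("menopause_percentiles.csv"))
  write_percentiles_csv(
    meno_percentiles(tf0,
                     profiles = tibble::tibble(bmi_category = "normal",
                                               smoker = 0L)),
    p("menopause_percentiles_no_covariates.csv"))

  if (is.null(predict_inputs)) {
    predict_inputs <- tibble::tibble(age_years = 30, amh_ng_ml = 2.5,
                                     bmi = 22, smoker = 0L)
  }
  preds <- predict_menopause(tf, age = predict_inputs$age_years,
                             amh = predict_inputs$amh_ng_ml,
                             bmi = predict_inputs$bmi,
                             smoker = predict_inputs$smoker)
  readr::write_csv(preds, p("predictions.csv"))
  write_report(prediction_report(preds, tf), p("prediction_report.json"))

  files <- c("amh_cohort.csv", "menopause_cohort.csv", "config_echo.json",
             "fitted_params.json", "amh_centiles.csv", "thresholds.csv",
             "menopause_percentiles.csv",
             "menopause_percentiles_no_covariates.csv", "predictions.csv",
             "prediction_report.json")
  manifest <- list(
    schema = "menothresh-manifest", schema_version = 1L,
    package_version = as.character(utils::packageVersion("menothresh")),
    seeds = list(amh_cohort = cfg$seed, menopause_cohort = cfg$seed + 1L),
    loglik = list(stage1 = af$loglik, stage2 = tf$loglik,
                  stage2_no_covariates = tf0$loglik),
    converged = list(stage1 = af$converged, stage2 = tf$converged),
    file_digests = stats::setNames(
      lapply(files, function(f) rlang::hash(readLines(p(f), warn = FALSE))),
      files))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  say("wrote %d artifacts to %s", length(files) + 1L, out_dir)
  invisible(manifest)
}
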
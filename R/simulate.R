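#' Configuration for the paired synthetic cohorts
#'
#' Bundles every generative parameter for the two synthetic cohorts: an AMH
#' cohort of eumenorrheic women (age, serum AMH, BMI, smoking) and a
#' menopausal-age cohort (age at menopause, BMI category, smoking). Defaults
#' reproduce the published cohort structure: n = 375 AMH records with ages
#' uniform on 19-44 y, BMI normal(23.2, 4.2) truncated at 15, 33.5% smokers;
#' n = 2635 menopause records with 27.6% smokers and BMI-category weights
#' placing 15/2635 in under-weight and 80% in normal + over-weight combined
#' (split 0.45/0.35); per-profile AMH thresholds at their published point
#' estimates; variance ratio kappa = 0.72. The regression coefficients and
#' residual scales come from [calibrate_defaults()].
#'
#' @param seed Integer seed driving all randomness downstream.
#' @param n_amh,n_meno Cohort sizes.
#' @param age_range AMH-cohort age range (years), sampled uniformly.
#' @param bmi_mean,bmi_sd AMH-cohort BMI distribution (kg/m^2).
#' @param smoke_prob_amh,smoke_prob_meno Smoking probabilities per cohort.
#' @param bmi_category_probs Named 4-vector of BMI-category probabilities for
#'   the menopause cohort (must sum to 1).
#' @param thresholds Named 8-vector of per-profile AMH thresholds (ng/mL).
#' @param calibration Output of [calibrate_defaults()] (regression
#'   coefficients, shapes, scales, kappa).
#' @return An object of class `meno_config`.
#' @examples
#' cfg <- meno_config(seed = 1)
#' cohort <- simulate_amh_cohort(cfg)
#' @export
meno_config <- function(seed = 1L,
                        n_amh = 375L,
                        n_meno = 2635L,
                        age_range = c(19, 44),
                        bmi_mean = 23.2,
                        bmi_sd = 4.2,
                        smoke_prob_amh = 0.335,
                        smoke_prob_meno = 0.276,
                        bmi_category_probs = c(under = 15 / 2635,
                                               normal = 0.45,
                                               over = 0.35,
                                               obese = 1 - 15 / 2635 - 0.80),
                        thresholds = default_thresholds(),
                        calibration = calibrate_defaults()) {
  stopifnot(n_amh >= 1, n_meno >= 1, length(age_range) == 2,
            diff(age_range) > 0, bmi_sd > 0,
            smoke_prob_amh >= 0, smoke_prob_amh <= 1,
            smoke_prob_meno >= 0, smoke_prob_meno <= 1,
            length(bmi_category_probs) == 4,
            all(bmi_category_probs >= 0),
            abs(sum(bmi_category_probs) - 1) < 1e-8,
            all(thresholds > 0), length(thresholds) == 8,
            abs(seed) < 2^31)
  names(bmi_category_probs) <- bmi_levels
  names(thresholds) <- names(default_thresholds())
  structure(list(seed = as.integer(seed), n_amh = as.integer(n_amh),
                 n_meno = as.integer(n_meno), age_range = age_range,
                 bmi_mean = bmi_mean, bmi_sd = bmi_sd,
                 smoke_prob_amh = smoke_prob_amh,
                 smoke_prob_meno = smoke_prob_meno,
                 bmi_category_probs = bmi_category_probs,
                 thresholds = thresholds,
                 calibration = calibration),
            class = "meno_config")
}

#' Generating-parameter threshold model implied by a configuration
#'
#' @param cfg A [meno_config()] object.
#' @return The [meno_model()] the generator samples from.
#' @export
as_meno_model <- function(cfg) {
  stopifnot(inherits(cfg, "meno_config"))
  cal <- cfg$calibration
  meno_model(coefs = cal$coefs, shape_a = cal$shape_a, shape_b = cal$shape_b,
             scale2 = cal$scale2, log_thresholds = log(cfg$thresholds),
             kappa = cal$kappa)
}

#' Simulate an AMH cohort
#'
#' Ages are uniform on the configured range, BMI is normal truncated at
#' 15 kg/m^2, smoking is Bernoulli, and `log(AMH)` is the quadratic age mean
#' plus a mean-zero skew-t deviate with the stage-1 scale
#' (`scale2 / sqrt(kappa)`).
#'
#' @param cfg A [meno_config()] object.
#' @param n Number of records (default `cfg$n_amh`).
#' @param seed Integer seed (default `cfg$seed`).
#' @return A tibble with columns `subject_id`, `age_years`, `amh_ng_ml`,
#'   `bmi`, `smoker`.
#' @export
simulate_amh_cohort <- function(cfg, n = cfg$n_amh, seed = cfg$seed) {
  stopifnot(inherits(cfg, "meno_config"), n >= 1)
  cal <- cfg$calibration
  res1 <- skt_mean_zero(skt_params(0, cal$scale1, cal$shape_a, cal$shape_b))
  with_preserved_seed(seed, {
    age <- stats::runif(n, cfg$age_range[1], cfg$age_range[2])
    bmi <- stats::rnorm(n, cfg$bmi_mean, cfg$bmi_sd)
    while (any(bad <- bmi < 15)) {
      bmi[bad] <- stats::rnorm(sum(bad), cfg$bmi_mean, cfg$bmi_sd)
    }
    smoker <- stats::rbinom(n, 1, cfg$smoke_prob_amh)
    log_amh <- mu_age(cal$coefs, age) + rskt(n, res1)
    tibble::tibble(subject_id = sprintf("A%04d", seq_len(n)),
                   age_years = age, amh_ng_ml = exp(log_amh),
                   bmi = bmi, smoker = as.integer(smoker))
  })
}

# Menopausal ages for given profiles, sampled by inverting the threshold-model
# CDF in closed form (the quadratic mean makes mu(y) = target solvable
# directly); draws outside the accepted (35, 65) record range are redrawn.
sample_meno_ages <- function(model, keys) {
  n <- length(keys)
  lth <- model$log_thresholds[keys]
  res <- model$residual
  out <- rep(NA_real_, n)
  need <- rep(TRUE, n)
  guard <- 0
  while (any(need)) {
    k <- sum(need)
    u <- stats::runif(k)
    # age solving mu(y) = log(theta) - Q2(u), taking the root above the peak
    tgt <- lth[need] - qskt(u, res)
    cc <- model$coefs
    disc <- cc[["age"]]^2 - 4 * cc[["age2"]] * (cc[["intercept"]] - tgt)
    y <- ifelse(disc > 0,
                (-cc[["age"]] - sqrt(pmax(disc, 0))) / (2 * cc[["age2"]]),
                NA_real_)
    ok <- !is.na(y) & y > 35 & y < 65
    idx <- which(need)
    out[idx[ok]] <- y[ok]
    need[idx[ok]] <- FALSE
    guard <- guard + 1
    if (guard > 1000) stop("menopausal-age sampler failed to converge")
  }
  out
}

#' Simulate a menopausal-age cohort
#'
#' Each woman's BMI category and smoking status are sampled from the
#' configured marginals; her age at menopause is then drawn from the
#' threshold-model distribution for that profile (AMH crossing below the
#' profile's threshold), restricted to the accepted record range (35, 65)
#' years by redrawing.
#'
#' @inheritParams simulate_amh_cohort
#' @param n Number of records (default `cfg$n_meno`).
#' @return A tibble with columns `subject_id`, `age_menopause_years`,
#'   `bmi_category`, `smoker`.
#' @export
simulate_menopause_cohort <- function(cfg, n = cfg$n_meno, seed = cfg$seed) {
  stopifnot(inherits(cfg, "meno_config"), n >= 1)
  model <- as_meno_model(cfg)
  with_preserved_seed(seed + 1L, {
    cat_i <- sample(bmi_levels, n, replace = TRUE, prob = cfg$bmi_category_probs)
    smoker <- stats::rbinom(n, 1, cfg$smoke_prob_meno)
    ages <- sample_meno_ages(model, profile_key(cat_i, smoker))
    tibble::tibble(subject_id = sprintf("M%05d", seq_len(n)),
                   age_menopause_years = ages,
                   bmi_category = cat_i, smoker = as.integer(smoker))
  })
}
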
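#' Calibrate default generating parameters from published anchor values
#'
#' The package's default model is anchored to printed summaries rather than to
#' raw data (which are not deposited): the reference AMH threshold for
#' normal-weight non-smokers (0.31 ng/mL), three percentiles of their
#' menopausal-age distribution (10th 44.2 y, 50th 49.5 y, 90th 53.6 y), a
#' quadratic log-AMH mean peaking at age 25, and a median AMH of about
#' 3 ng/mL at age 30.
#'
#' Writing `mu(y) = c0 + c1 y + c2 y^2` with `c1 = -2 c2 * peak_age`, each
#' percentile anchor `(p, y_p)` imposes the linear constraint
#' `mu(y_p) + scale2 * (q(p) - m) = log(threshold_ref)`, where `q` is the
#' standard skew-t quantile function and `m` its mean (the residual law is
#' mean zero). Because the right-hand side is the same for all three anchors,
#' a non-degenerate solution exists only when the skew-t quantile spacing
#' ratio `(q(.9)-q(.5)) / (q(.5)-q(.1))` matches the spacing ratio of the age
#' polynomial at the anchor ages; the shape `b` is therefore solved from that
#' ratio with the left-tail shape `a` held fixed. The remaining free scale is
#' pinned by the AMH anchor: the stage-1 median AMH at `amh_anchor_age` equals
#' `median_amh_anchor`, with the stage-1 scale inflated from the stage-2 scale
#' by `1/sqrt(kappa)` (excess inter- and intra-cycle variation in measured
#' AMH does not contribute to menopause timing).
#'
#' @param anchor_probs,anchor_ages Percentile anchors for the reference
#'   profile (probabilities and menopausal ages in years).
#' @param threshold_ref Reference AMH threshold in ng/mL (normal-weight
#'   non-smoker).
#' @param peak_age Age in years at which the quadratic log-AMH mean peaks.
#' @param amh_anchor_age,median_amh_anchor Age (years) and median AMH (ng/mL)
#'   anchoring the stage-1 scale.
#' @param shape_a Fixed left-tail shape of the skew-t residual laws.
#' @param kappa Stage-2 to stage-1 residual variance ratio (< 1 means the
#'   variation relevant to menopause timing is smaller than the
#'   cross-sectional residual variation).
#' @return A list with components `coefs` (named `intercept`, `age`, `age2`),
#'   `shape_a`, `shape_b`, `scale1`, `scale2`, `kappa`, `peak_age`.
#' @examples
#' cal <- calibrate_defaults()
#' cal$coefs
#' @export
calibrate_defaults <- function(anchor_probs = c(0.10, 0.50, 0.90),
                               anchor_ages = c(44.2, 49.5, 53.6),
                               threshold_ref = 0.31,
                               peak_age = 25,
                               amh_anchor_age = 30,
                               median_amh_anchor = 3.0,
                               shape_a = 2,
                               kappa = 0.72) {
  stopifnot(length(anchor_probs) == 3, length(anchor_ages) == 3,
            all(diff(anchor_probs) > 0), all(diff(anchor_ages) > 0),
            threshold_ref > 0, kappa > 0, shape_a > 0.5001)
  g <- function(y) y^2 - 2 * peak_age * y  # quadratic term with c1 tied to c2
  ratio_target <- (g(anchor_ages[2]) - g(anchor_ages[3])) /
    (g(anchor_ages[1]) - g(anchor_ages[2]))
  spacing <- function(b) {
    q <- skt_std_quantile(anchor_probs, shape_a, b)
    (q[3] - q[2]) / (q[2] - q[1])
  }
  b <- tryCatch(
    stats::uniroot(function(b) spacing(b) - ratio_target,
                   c(shape_a * 1.00005, 1000), tol = 1e-12)$root,
    error = function(e) stop("anchor constraint system has no skew-t shape ",
                             "solution for shape_a = ", shape_a, ": ",
                             conditionMessage(e))
  )
  m <- skt_std_mean(shape_a, b)
  qa <- skt_std_quantile(anchor_probs, shape_a, b) - m
  r12 <- (qa[2] - qa[1]) / (g(anchor_ages[2]) - g(anchor_ages[1]))
  # mu(y) = c0 + c2 * g(y) with c2 = -scale2 * r12; pin scale2 from AMH anchor
  denom <- r12 * g(anchor_ages[2]) - qa[2] - r12 * g(amh_anchor_age) +
    qa[2] / sqrt(kappa)
  if (abs(denom) < 1e-12) stop("calibration constraint system is singular")
  scale2 <- (log(median_amh_anchor) - log(threshold_ref)) / denom
  if (scale2 <= 0) stop("calibration produced a non-positive stage-2 scale")
  c2 <- -scale2 * r12
  c0 <- log(threshold_ref) + scale2 * (r12 * g(anchor_ages[2]) - qa[2])
  c1 <- -2 * peak_age * c2
  scale1 <- scale2 / sqrt(kappa)
  # sanity: implied median AMH near age 30 must sit in the plausible window
  med30 <- exp(c0 + c1 * 30 + c2 * 900 + scale1 * (skt_std_quantile(0.5, shape_a, b) - m))
  if (med30 < 2.5 || med30 > 3.5) {
    stop(sprintf("calibration sanity check failed: implied median AMH at 30 is %.2f ng/mL (expected 2.5-3.5)", med30))
  }
  list(coefs = c(intercept = c0, age = c1, age2 = c2),
       shape_a = shape_a, shape_b = b,
       scale1 = scale1, scale2 = scale2,
       kappa = kappa, peak_age = peak_age)
}

bmi_levels <- c("under", "normal", "over", "obese")

#' Classify continuous BMI into the standard categories
#'
#' Cut-points: under-weight < 18.5, normal 18.5 to < 25, over-weight 25 to
#' < 30, obese >= 30 kg/m^2.
#'
#' @param bmi Numeric vector of BMI values in kg/m^2.
#' @return A character vector with values in
#'   `c("under", "normal", "over", "obese")`.
#' @export
bmi_category <- function(bmi) {
  if (any(!is.finite(bmi) | bmi <= 10)) stop("BMI values must be finite and > 10")
  cut(bmi, breaks = c(-Inf, 18.5, 25, 30, Inf), right = FALSE,
      labels = bmi_levels) |> as.character()
}

# internal alias: usable where a `bmi_category` argument shadows the function
classify_bmi <- function(bmi) bmi_category(bmi)

profile_key <- function(bmi_category, smoker) {
  stopifnot(all(bmi_category %in% bmi_levels), all(smoker %in% c(0, 1)))
  paste0(bmi_category, "_", ifelse(smoker == 1, "smoker", "nonsmoker"))
}

#' The eight BMI-by-smoking covariate profiles
#'
#' @return A tibble with columns `bmi_category` and `smoker` enumerating the
#'   four BMI categories crossed with smoking status (0 = never, 1 = current
#'   or past).
#' @export
covariate_profiles <- function() {
  tidyr::expand_grid(bmi_category = bmi_levels, smoker = c(0L, 1L))
}

# default per-profile AMH thresholds (ng/mL)
default_thresholds <- function() {
  c(under_nonsmoker = 0.45, under_smoker = 0.53,
    normal_nonsmoker = 0.31, normal_smoker = 0.36,
    over_nonsmoker = 0.25, over_smoker = 0.30,
    obese_nonsmoker = 0.28, obese_smoker = 0.33)
}

#' Assemble a menopause threshold model from raw parameters
#'
#' A `meno_model` is the minimal parameter set needed to evaluate the
#' menopausal-age distribution: the quadratic log-AMH mean coefficients, the
#' skew-t shape pair, the stage-2 scale, and one log-threshold per covariate
#' profile. Both the synthetic-data generator (with generating parameters) and
#' [fit_threshold()] (with estimates) produce one.
#'
#' @param coefs Named numeric vector `c(intercept, age, age2)` with `age2 < 0`.
#' @param shape_a,shape_b Skew-t shape parameters shared by both stages.
#' @param scale2 Stage-2 residual scale (log ng/mL).
#' @param log_thresholds Named numeric vector of log-thresholds, one per
#'   profile key as produced by `covariate_profiles()`.
#' @param kappa Stage-2 : stage-1 variance ratio.
#' @return An object of class `meno_model`.
#' @export
meno_model <- function(coefs, shape_a, shape_b, scale2, log_thresholds,
                       kappa = NA_real_) {
  stopifnot(length(coefs) == 3, is.finite(coefs), coefs[3] < 0,
            is.finite(scale2), scale2 > 0)
  keys <- profile_key(covariate_profiles()$bmi_category,
                      covariate_profiles()$smoker)
  if (!all(keys %in% names(log_thresholds))) {
    stop("`log_thresholds` must be named for all 8 covariate profiles")
  }
  names(coefs) <- c("intercept", "age", "age2")
  structure(list(coefs = coefs,
                 residual = skt_mean_zero(skt_params(0, scale2, shape_a, shape_b)),
                 log_thresholds = log_thresholds[keys],
                 kappa = kappa,
                 peak_age = -coefs[["age"]] / (2 * coefs[["age2"]])),
            class = "meno_model")
}

#' @export
print.meno_model <- function(x, ...) {
  cat("Menopause threshold model\n")
  cat(sprintf("  mean log(AMH): %.4g %+.4g*age %+.4g*age^2  (peak at %.2f y)\n",
              x$coefs[1], x$coefs[2], x$coefs[3], x$peak_age))
  cat(sprintf("  stage-2 residual scale %.4g, shapes (%.4g, %.4g), kappa %.3g\n",
              x$residual$scale, x$residual$a, x$residual$b, x$kappa))
  cat("  thresholds (ng/mL):\n")
  print(round(exp(x$log_thresholds), 3))
  invisible(x)
}

mu_age <- function(coefs, age) coefs[[1]] + coefs[[2]] * age + coefs[[3]] * age^2
mu_slope <- function(coefs, age) coefs[[2]] + 2 * coefs[[3]] * age
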
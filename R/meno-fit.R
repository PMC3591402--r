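#' Distribution of age at menopause under the threshold model
#'
#' The threshold model equates "menopause before age y" with "AMH at age y
#' below the profile's critical threshold": the cumulative probability is the
#' stage-2 skew-t distribution function evaluated at
#' `log(threshold) - mu(y)`, where `mu` is the stage-1 mean of log(AMH).
#' `meno_cdf` is only defined beyond the age at which `mu` peaks (the mean is
#' non-monotone before it) and tends to 1 as age grows. `meno_pdf` is its
#' derivative, `dskt(log theta - mu(y)) * (-mu'(y))`.
#'
#' @param object A [meno_model()], a `threshold_fit`, or a [meno_config()].
#' @param age Vector of ages in years, all strictly above the peak age.
#' @param bmi_category BMI category, one of
#'   `c("under", "normal", "over", "obese")` (recycled).
#' @param smoker 0 (never) or 1 (current or past), recycled.
#' @return Probabilities (`meno_cdf`) or densities (`meno_pdf`).
#' @examples
#' m <- as_meno_model(meno_config())
#' meno_cdf(m, c(45, 50, 55))
#' @export
meno_cdf <- function(object, age, bmi_category = "normal", smoker = 0L) {
  model <- resolve_meno_model(object)
  if (any(age <= model$peak_age)) {
    stop(sprintf("ages must exceed the peak age %.2f y: the mean log(AMH) is non-monotone below it", model$peak_age))
  }
  lth <- model$log_thresholds[profile_key(bmi_category, smoker)]
  unname(pskt(lth - mu_age(model$coefs, age), model$residual))
}

#' @rdname meno_cdf
#' @export
meno_pdf <- function(object, age, bmi_category = "normal", smoker = 0L) {
  model <- resolve_meno_model(object)
  if (any(age <= model$peak_age)) {
    stop(sprintf("ages must exceed the peak age %.2f y", model$peak_age))
  }
  lth <- model$log_thresholds[profile_key(bmi_category, smoker)]
  unname(dskt(lth - mu_age(model$coefs, age), model$residual) *
           (-mu_slope(model$coefs, age)))
}

resolve_meno_model <- function(object) {
  if (inherits(object, "meno_model")) return(object)
  if (inherits(object, "threshold_fit")) return(object$model)
  if (inherits(object, "meno_config")) return(as_meno_model(object))
  stop("expected a meno_model, threshold_fit or meno_config")
}

#' Percentiles of age at menopause per covariate profile
#'
#' For each profile and probability, the age solving `meno_cdf(age) = prob`
#' by monotone root-finding on `(peak_age + 0.5, 80)` years.
#'
#' @param object A [meno_model()], `threshold_fit`, or [meno_config()].
#' @param probs Probabilities (strictly inside (0, 1)).
#' @param profiles Tibble of `bmi_category`, `smoker` rows (default: all 8).
#' @return A tibble with `bmi_category`, `smoker`, `prob`, `age_years`,
#'   strictly increasing in `prob` within each profile.
#' @examples
#' meno_percentiles(meno_config(), probs = 0.5)
#' @export
meno_percentiles <- function(object,
                             probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95),
                             profiles = covariate_profiles()) {
  model <- resolve_meno_model(object)
  stopifnot(all(probs > 0), all(probs < 1))
  lo <- model$peak_age + 0.5
  hi <- 80
  out <- tidyr::expand_grid(profiles, prob = sort(probs))
  out$age_years <- purrr::pmap_dbl(out, function(bmi_category, smoker, prob) {
    f <- function(y) meno_cdf(model, y, bmi_category, smoker) - prob
    if (f(lo) > 0 || f(hi) < 0) {
      stop(sprintf("percentile %g not bracketed on (%.1f, %.0f) for profile %s",
                   prob, lo, hi, profile_key(bmi_category, smoker)))
    }
    stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  })
  out
}

validate_meno_data <- function(data) {
  data <- tibble::as_tibble(data)
  req <- c("age_menopause_years", "bmi_category", "smoker")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("menopause data is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(data$age_menopause_years) |
                 data$age_menopause_years <= 35 |
                 data$age_menopause_years >= 65)
  if (length(bad)) {
    stop("age at menopause outside the accepted range (35, 65) at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "")
  }
  if (!all(data$bmi_category %in% bmi_levels)) {
    stop("bmi_category must be one of: ", paste(bmi_levels, collapse = ", "))
  }
  if (!all(data$smoker %in% c(0, 1))) stop("smoker must be 0 or 1")
  data
}

#' Fit the covariate-dependent AMH threshold model
#'
#' Stage two: with the stage-1 regression fixed, maximizes the likelihood of
#' observed menopausal ages under the threshold-crossing density over the
#' reference log-threshold `alpha` (normal-weight non-smoker), additive BMI
#' offsets (`under`, `over`, `obese`), an additive smoking offset, and the
#' variance ratio `kappa` linking the stage-2 scale to the stage-1 residual
#' scale (`scale2 = scale1 * sqrt(kappa)`, estimated on the log scale). The
#' skew-t shapes are shared with stage 1. Because records are only accepted
#' with menopausal ages in (35, 65), the likelihood conditions on that
#' observation window (each contribution is normalized by the window
#' probability for the record's profile); without this the tail truncation
#' biases the threshold and `kappa` estimates. A weak quartic penalty on the
#' covariate offsets (negligible below 1 log-unit) rules out a degenerate
#' likelihood plateau in which a sparse stratum's offset runs away; the
#' reported `loglik` is the unpenalized value.
#'
#' @param data Menopause records (`age_menopause_years` in (35, 65),
#'   `bmi_category`, `smoker`).
#' @param amh_fit A fitted [fit_amh()] model with an age-only quadratic mean.
#' @param method `"two_stage"` (stage 1 fixed; default) or `"joint"`
#'   (stage-1 parameters re-estimated jointly with stage 2 by maximizing the
#'   summed likelihood of both cohorts).
#' @param censoring `"none"` treats reported ages as exact (default);
#'   `"interval"` uses a +/- 0.5-year interval-censored likelihood for ages
#'   recalled in whole years.
#' @param reltol Convergence tolerance.
#' @param start Optional 6-vector of starting values
#'   `(alpha, beta_under, beta_over, beta_obese, gamma_smoke, log kappa)`;
#'   when supplied a single optimization is run from it (used to warm-start
#'   bootstrap refits).
#' @param covariates If `FALSE`, fits the threshold with no BMI or smoking
#'   dependence (a single threshold and `kappa` only), as in modelling that
#'   ignores these covariates.
#' @return An object of class `threshold_fit` with the additive parameters,
#'   `kappa`, the implied per-profile thresholds, `loglik`, `n`, and the
#'   records (retained for diagnostics and bootstrapping).
#' @examples
#' cfg <- meno_config(seed = 1)
#' af <- fit_amh(simulate_amh_cohort(cfg))
#' tf <- fit_threshold(simulate_menopause_cohort(cfg, n = 500), af)
#' tidy(tf)
#' @export
fit_threshold <- function(data, amh_fit, method = c("two_stage", "joint"),
                          censoring = c("none", "interval"), reltol = 1e-10,
                          start = NULL, covariates = TRUE) {
  method <- match.arg(method)
  censoring <- match.arg(censoring)
  stopifnot(inherits(amh_fit, "amh_fit"))
  if (length(amh_fit$terms)) {
    stop("stage-2 fitting requires a stage-1 model with the plain quadratic age mean")
  }
  data <- validate_meno_data(data)
  if (nrow(data) < 100) stop("need at least 100 menopause records to fit")
  if (covariates) {
    counts <- table(factor(data$bmi_category, levels = bmi_levels))
    empty <- names(counts)[counts == 0 & names(counts) != "normal"]
    if (length(empty)) {
      stop("threshold offset unidentifiable for empty BMI categor",
           if (length(empty) > 1) "ies: " else "y: ",
           paste(empty, collapse = ", "))
    }
    if (length(unique(data$smoker)) < 2) {
      stop("smoking offset unidentifiable: all records share one smoking status")
    }
  }
  coefs <- amh_fit$coefficients[c("intercept", "age", "age2")]
  pk <- peak_age(amh_fit)
  if (any(data$age_menopause_years <= pk)) {
    stop(sprintf("menopausal ages at or below the fitted peak age %.2f y are incompatible with the threshold model", pk))
  }
  a <- amh_fit$residual$a
  b <- amh_fit$residual$b
  s1 <- amh_fit$residual$scale
  y <- data$age_menopause_years
  cat_idx <- match(data$bmi_category, bmi_levels)
  sm <- data$smoker
  muy <- mu_age(coefs, y)
  mup <- mu_slope(coefs, y)
  mstd <- skt_std_mean(a, b)

  expand_par <- function(par) {
    if (covariates) par else c(par[1], 0, 0, 0, 0, par[2])
  }
  # records are only accepted on (35, 65), so the likelihood conditions on
  # that observation window: each contribution is divided by F(65) - F(35)
  # for the record's profile (computed once per profile, not per record)
  prof_idx <- (cat_idx - 1L) * 2L + sm + 1L
  cat_u <- rep(seq_len(4), each = 2)
  sm_u <- rep(c(0, 1), 4)
  mu35 <- mu_age(coefs, 35)
  mu65 <- mu_age(coefs, 65)
  stage2_negll <- function(parb) {
    par <- expand_par(parb)
    lth_u <- par[1] + c(par[2], 0, par[3], par[4])[cat_u] + par[5] * sm_u
    s2 <- s1 * sqrt(exp(par[6]))
    w35 <- skt_std_cdf((lth_u - mu35) / s2 + mstd, a, b)
    w65 <- skt_std_cdf((lth_u - mu65) / s2 + mstd, a, b)
    win <- w65 - w35
    # all observed ages lie inside (35, 65); parameters placing almost no
    # mass there are rejected rather than risking log-of-underflow spikes
    if (any(!is.finite(win)) || any(win < 1e-6)) return(1e10)
    lth <- lth_u[prof_idx]
    lwin <- log(win)[prof_idx]
    if (censoring == "none") {
      z <- (lth - muy) / s2 + mstd
      v <- -sum(skt_std_logpdf(z, a, b) - log(s2) + log(-mup) - lwin)
    } else {
      res <- skt_params(-s2 * mstd, s2, a, b)
      yl <- pmax(y - 0.5, pk + 1e-6)
      lo <- pskt(lth - mu_age(coefs, yl), res)
      hi <- pskt(lth - mu_age(coefs, y + 0.5), res)
      v <- -sum(log(pmax(hi - lo, 1e-300)) - lwin)
    }
    # weak quartic regularization of the covariate offsets: the window
    # conditioning creates a likelihood plateau as an offset for a sparse
    # stratum runs away (all mass pushed outside the window); the penalty is
    # negligible for offsets below 1 log-unit and prohibitive beyond ~1.5
    v <- v + sum(par[2:5]^4)
    if (!is.finite(v)) 1e10 else v
  }

  # data-driven start: reference threshold from the median menopausal age
  s2_0 <- s1 * sqrt(0.72)
  alpha0 <- mu_age(coefs, stats::median(y)) +
    s2_0 * (skt_std_quantile(0.5, a, b) - mstd)
  starts <- if (!is.null(start)) {
    list(if (covariates) start else start[c(1, 6)])
  } else if (covariates) {
    list(c(alpha0, 0, 0, 0, 0, log(0.72)), c(alpha0, 0, 0, 0, 0, log(1.2)))
  } else {
    list(c(alpha0, log(0.72)), c(alpha0, log(1.2)))
  }
  best <- NULL
  for (st in starts) {
    o <- tryCatch(
      stats::optim(st, stage2_negll, method = "BFGS",
                   control = list(maxit = 2000, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best) || best$convergence != 0) {
    stop("threshold-model fit did not converge",
         if (!is.null(best)) paste0(" (optim code ", best$convergence, ")"))
  }
  # warm-started refits (bootstrap) begin at a near-optimal point and a
  # single quasi-Newton run suffices; cold fits get the full polish
  if (is.null(start)) best <- polish_optim(best, stage2_negll, reltol)

  par <- unname(expand_par(best$par))
  loglik <- -best$value + sum(par[2:5]^4)  # report the unpenalized loglik

  if (method == "joint" && !covariates) {
    stop("the joint fit requires `covariates = TRUE`")
  }
  if (method == "joint") {
    jt <- fit_joint(data, amh_fit, par, censoring, reltol)
    amh_fit <- jt$amh_fit
    par <- jt$par
    loglik <- jt$loglik
    coefs <- amh_fit$coefficients[c("intercept", "age", "age2")]
    a <- amh_fit$residual$a; b <- amh_fit$residual$b
    s1 <- amh_fit$residual$scale
  }

  kappa <- exp(par[6])
  s2 <- s1 * sqrt(kappa)
  beta <- c(under = par[2], over = par[3], obese = par[4])
  lth_all <- par[1] + c(under = par[2], normal = 0, over = par[3],
                        obese = par[4])[rep(bmi_levels, each = 2)] +
    par[5] * rep(c(0, 1), 4)
  names(lth_all) <- profile_key(rep(bmi_levels, each = 2), rep(c(0, 1), 4))
  model <- meno_model(coefs = coefs, shape_a = a, shape_b = b, scale2 = s2,
                      log_thresholds = lth_all, kappa = kappa)
  structure(list(alpha = par[1], beta_bmi = beta, gamma_smoke = par[5],
                 kappa = kappa,
                 stage2_residual = model$residual,
                 loglik = loglik, n = nrow(data),
                 n_params = if (covariates) 6L else 2L,
                 converged = TRUE, method = method, censoring = censoring,
                 model = model, amh_fit = amh_fit, data = data),
            class = "threshold_fit")
}

# Joint maximization of the stage-1 (AMH cohort) and stage-2 (menopause
# cohort) log-likelihoods; stage-2 two-stage estimates serve as starts.
fit_joint <- function(data, amh_fit, par2, censoring, reltol) {
  ad <- amh_fit$data
  X <- amh_design(ad, character())
  ylog <- log(ad$amh_ng_ml)
  ym <- data$age_menopause_years
  cat_idx <- match(data$bmi_category, bmi_levels)
  sm <- data$smoker
  negll <- function(p) {
    beta1 <- p[1:3]; s1 <- exp(p[4]); a <- 0.5 + exp(p[5]); b <- 0.5 + exp(p[6])
    mstd <- skt_std_mean(a, b)
    t1 <- (ylog - drop(X %*% beta1)) / s1 + mstd
    ll1 <- sum(skt_std_logpdf(t1, a, b) - log(s1))
    pk <- -beta1[2] / (2 * beta1[3])
    if (beta1[3] >= 0 || any(ym <= pk)) return(1e10)
    lth <- p[7] + c(p[8], 0, p[9], p[10])[cat_idx] + p[11] * sm
    s2 <- s1 * sqrt(exp(p[12]))
    muy <- beta1[1] + beta1[2] * ym + beta1[3] * ym^2
    mup <- beta1[2] + 2 * beta1[3] * ym
    z <- (lth - muy) / s2 + mstd
    mu35 <- beta1[1] + beta1[2] * 35 + beta1[3] * 35^2
    mu65 <- beta1[1] + beta1[2] * 65 + beta1[3] * 65^2
    w35 <- skt_std_cdf((lth - mu35) / s2 + mstd, a, b)
    w65 <- skt_std_cdf((lth - mu65) / s2 + mstd, a, b)
    win <- w65 - w35
    if (any(!is.finite(win)) || any(win < 1e-6)) return(1e10)
    ll2 <- sum(skt_std_logpdf(z, a, b) - log(s2) + log(-mup) - log(win)) -
      sum(p[8:11]^4)
    v <- -(ll1 + ll2)
    if (!is.finite(v)) 1e10 else v
  }
  st <- c(amh_fit$coefficients[1:3], log(amh_fit$residual$scale),
          log(amh_fit$residual$a - 0.5), log(amh_fit$residual$b - 0.5), par2)
  o <- stats::optim(st, negll, method = "BFGS",
                    control = list(maxit = 3000, reltol = reltol))
  if (o$convergence != 0) stop("joint fit did not converge")
  o <- polish_optim(o, negll, reltol)
  p <- o$par
  s1 <- exp(p[4]); a <- 0.5 + exp(p[5]); b <- 0.5 + exp(p[6])
  af <- amh_fit
  af$coefficients <- c(intercept = p[1], age = p[2], age2 = p[3])
  af$residual <- skt_mean_zero(skt_params(0, s1, a, b))
  list(amh_fit = af, par = unname(p[7:12]), loglik = -o$value)
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("AMH threshold model for age at menopause  (n = %d, loglik = %.2f)\n",
              x$n, x$loglik))
  cat(sprintf("  reference threshold (normal weight, non-smoker): %.3f ng/mL\n",
              exp(x$alpha)))
  cat(sprintf("  BMI offsets (log ng/mL): under %+.3f, over %+.3f, obese %+.3f\n",
              x$beta_bmi[["under"]], x$beta_bmi[["over"]], x$beta_bmi[["obese"]]))
  cat(sprintf("  smoking offset: %+.3f   kappa (stage-2/stage-1 variance): %.3f\n",
              x$gamma_smoke, x$kappa))
  invisible(x)
}

#' @export
tidy.threshold_fit <- function(x, ...) {
  tibble::tibble(
    term = c("alpha", "beta_under", "beta_over", "beta_obese", "gamma_smoke",
             "kappa"),
    estimate = c(x$alpha, x$beta_bmi[["under"]], x$beta_bmi[["over"]],
                 x$beta_bmi[["obese"]], x$gamma_smoke, x$kappa))
}

#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_params = x$n_params,
                 kappa = x$kappa, converged = x$converged, method = x$method)
}

#' Observed versus model cumulative distribution of menopausal age
#'
#' For one covariate stratum, pairs the empirical cumulative distribution of
#' observed menopausal ages with the model-based distribution on a common age
#' grid and reports the Kolmogorov-Smirnov-type maximal gap. Strata with
#' fewer than 20 records are refused: no meaningful comparison can be made.
#'
#' @param data Menopause records.
#' @param object A `threshold_fit`, [meno_model()] or [meno_config()].
#' @param bmi_category,smoker The stratum to compare.
#' @return An object of class `meno_cdf_compare`: a list with `curves` (a
#'   tibble `age_years`, `empirical`, `model`), `max_gap`, `n`, and the
#'   stratum labels.
#' @export
meno_cdf_compare <- function(data, object, bmi_category, smoker) {
  model <- resolve_meno_model(object)
  data <- validate_meno_data(data)
  sub <- data[data$bmi_category == bmi_category & data$smoker == smoker, ]
  if (nrow(sub) < 20) {
    stop(sprintf("only %d records for profile %s: too few for a meaningful comparison (need >= 20)",
                 nrow(sub), profile_key(bmi_category, smoker)))
  }
  ys <- sort(sub$age_menopause_years)
  n <- length(ys)
  Fm <- meno_cdf(model, ys, bmi_category, smoker)
  gap <- max(abs(Fm - seq_len(n) / n), abs(Fm - (seq_len(n) - 1) / n))
  grid <- seq(min(ys) - 1, max(ys) + 1, length.out = 200)
  grid <- grid[grid > model$peak_age]
  curves <- tibble::tibble(age_years = grid,
                           empirical = stats::ecdf(ys)(grid),
                           model = meno_cdf(model, grid, bmi_category, smoker))
  structure(list(curves = curves, max_gap = gap, n = n,
                 bmi_category = bmi_category, smoker = smoker),
            class = "meno_cdf_compare")
}

#' @export
print.meno_cdf_compare <- function(x, ...) {
  cat(sprintf("Observed vs model CDF, %s (n = %d): max gap %.4f\n",
              profile_key(x$bmi_category, x$smoker), x$n, x$max_gap))
  invisible(x)
}

#' @export
autoplot.meno_cdf_compare <- function(object, ...) {
  long <- tidyr::pivot_longer(object$curves, c("empirical", "model"),
                              names_to = "curve", values_to = "cdf")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$age_years, y = .data$cdf,
                                     linetype = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Age at menopause (years)", y = "Cumulative probability",
                  title = sprintf("%s, smoker = %d (max gap %.3f)",
                                  object$bmi_category, object$smoker,
                                  object$max_gap))
}

#' Parametric bootstrap uncertainty for the threshold model
#'
#' Regenerates menopausal ages from the fitted model at the observed
#' covariate profiles, refits stage 2, and reports percentile-method 95%
#' intervals and standard errors for the per-profile thresholds, `kappa`,
#' and the menopausal-age percentiles. By default stage 1 is held at its
#' fitted values (the intervals quantify stage-2 uncertainty conditional on
#' stage 1); `refit_stage1 = TRUE` also regenerates the AMH cohort at its
#' observed ages and refits stage 1 in each replicate.
#'
#' @param fit A `threshold_fit`.
#' @param n_boot Number of bootstrap replicates (>= 100).
#' @param seed Integer seed; identical seeds give identical tables.
#' @param refit_stage1 Also bootstrap the stage-1 regression.
#' @param percentile_probs Menopausal-age percentiles to summarize.
#' @return A tibble with `term`, `estimate`, `se`, `conf.low`, `conf.high`.
#' @export
meno_bootstrap <- function(fit, n_boot = 200, seed = 1,
                           refit_stage1 = FALSE,
                           percentile_probs = c(0.10, 0.50, 0.90)) {
  stopifnot(inherits(fit, "threshold_fit"))
  if (n_boot < 100) stop("`n_boot` must be at least 100")
  keys <- profile_key(fit$data$bmi_category, fit$data$smoker)
  extract <- function(tf) {
    pc <- meno_percentiles(tf, probs = percentile_probs)
    c(exp(tf$model$log_thresholds),
      kappa = tf$kappa,
      stats::setNames(pc$age_years,
                      paste0("percentile_", profile_key(pc$bmi_category, pc$smoker),
                             "_p", formatC(100 * pc$prob, width = 2, flag = "0"))))
  }
  point <- extract(fit)
  names(point)[1:8] <- paste0("threshold_", names(fit$model$log_thresholds))
  draws <- with_preserved_seed(seed, {
    purrr::map(seq_len(n_boot), function(i) {
      bd <- fit$data
      bd$age_menopause_years <- sample_meno_ages(fit$model, keys)
      af <- fit$amh_fit
      if (refit_stage1) {
        ad <- af$data
        ad$amh_ng_ml <- exp(amh_mu(af, ad$age_years) +
                              rskt(nrow(ad), af$residual))
        af <- tryCatch(fit_amh(ad, n_starts = 2), error = function(e) NULL)
        if (is.null(af)) return(NULL)
      }
      tf <- tryCatch(
        fit_threshold(bd, af, censoring = fit$censoring,
                      start = c(fit$alpha, fit$beta_bmi[["under"]],
                                fit$beta_bmi[["over"]], fit$beta_bmi[["obese"]],
                                fit$gamma_smoke, log(fit$kappa))),
        error = function(e) NULL)
      if (is.null(tf)) return(NULL)
      out <- extract(tf)
      names(out)[1:8] <- paste0("threshold_", names(tf$model$log_thresholds))
      out
    })
  })
  ok <- !purrr::map_lgl(draws, is.null)
  if (mean(!ok) > 0.10) {
    stop(sprintf("bootstrap refit failed in %d of %d replicates (> 10%%)",
                 sum(!ok), n_boot))
  }
  mat <- do.call(rbind, draws[ok])
  tibble::tibble(term = names(point),
                 estimate = unname(point),
                 se = apply(mat, 2, stats::sd),
                 conf.low = apply(mat, 2, stats::quantile, probs = 0.025),
                 conf.high = apply(mat, 2, stats::quantile, probs = 0.975))
}
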
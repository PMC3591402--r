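#' Fit the skew-t regression of log(AMH) on age
#'
#' Stage one of the two-stage menopause model: maximum-likelihood regression
#' of `log(amh_ng_ml)` on a quadratic in age, with residuals following a
#' mean-zero Jones-Faddy skew-t law. The mean-zero constraint identifies the
#' regression function as the expectation: the skew-t location is tied to the
#' scale and shapes so that the residual mean is exactly zero, and only the
#' scale and the two shapes are free.
#'
#' Optimization is multi-start quasi-Newton (BFGS) on a transformed space
#' (log scale; `log(shape - 0.5)` for each shape, keeping shapes above the
#' mean-existence boundary), with regression starts from an ordinary
#' least-squares fit and a documented grid of shape starts covering
#' symmetric, left-skew, right-skew, heavy- and light-tailed laws. Skew-t
#' likelihoods can be multimodal in the shapes; the best of the starts is
#' kept.
#'
#' @param data A data frame with columns `age_years`, `amh_ng_ml` (positive)
#'   and, when used in `extra_terms`, `bmi` and `smoker`.
#' @param extra_terms Character vector of additional mean terms to test,
#'   from `c("age3", "age4", "bmi", "smoker", "bmi_age", "smoker_age")`
#'   (cubic/quartic age, main effects, and interactions with age).
#' @param n_starts Number of shape starting points (1-5).
#' @param reltol Relative convergence tolerance on the log-likelihood.
#' @return An object of class `amh_fit`: coefficients, the mean-zero skew-t
#'   residual law, `loglik`, `n`, `n_params`, convergence diagnostics, and
#'   the data (retained for nested testing and diagnostics).
#' @examples
#' cfg <- meno_config(seed = 1)
#' fit <- fit_amh(simulate_amh_cohort(cfg))
#' glance(fit)
#' @export
fit_amh <- function(data, extra_terms = NULL, n_starts = 5, reltol = 1e-8) {
  data <- validate_amh_data(data, need = extra_terms)
  if (nrow(data) < 30) stop("need at least 30 AMH records to fit")
  known <- c("age3", "age4", "bmi", "smoker", "bmi_age", "smoker_age")
  if (!all(extra_terms %in% known)) {
    stop("unknown extra_terms: ",
         paste(setdiff(extra_terms, known), collapse = ", "))
  }
  X <- amh_design(data, extra_terms)
  y <- log(data$amh_ng_ml)
  k <- ncol(X)

  negll <- function(par) {
    beta <- par[1:k]
    s <- exp(par[k + 1])
    a <- 0.5 + exp(par[k + 2])
    b <- 0.5 + exp(par[k + 3])
    t <- (y - drop(X %*% beta)) / s + skt_std_mean(a, b)
    v <- -sum(skt_std_logpdf(t, a, b) - log(s))
    if (!is.finite(v)) 1e10 else v
  }

  lmf <- stats::lm.fit(X, y)
  start_beta <- lmf$coefficients
  start_logs <- log(stats::sd(lmf$residuals))
  shape_starts <- list(c(3, 3), c(2, 5), c(5, 2), c(1.5, 1.5), c(8, 8))
  shape_starts <- shape_starts[seq_len(max(1, min(n_starts, 5)))]
  best <- NULL
  for (sh in shape_starts) {
    st <- c(start_beta, start_logs, log(sh - 0.5))
    o <- tryCatch(
      stats::optim(st, negll, method = "BFGS",
                   control = list(maxit = 1000, reltol = reltol)),
      error = function(e) NULL)
    if (!is.null(o) && (is.null(best) || o$value < best$value)) best <- o
  }
  if (is.null(best)) stop("skew-t regression failed: no start converged")
  best <- polish_optim(best, negll, reltol)
  if (best$convergence != 0) {
    stop("skew-t regression did not converge (optim code ", best$convergence,
         "); counts: ", paste(best$counts, collapse = "/"))
  }
  beta <- best$par[1:k]
  names(beta) <- colnames(X)
  s <- exp(best$par[k + 1])
  a <- 0.5 + exp(best$par[k + 2])
  b <- 0.5 + exp(best$par[k + 3])
  structure(list(coefficients = beta,
                 residual = skt_mean_zero(skt_params(0, s, a, b)),
                 loglik = -best$value,
                 n = nrow(data),
                 n_params = k + 3,
                 terms = extra_terms %||% character(),
                 converged = TRUE,
                 optim_counts = best$counts,
                 validity_range = c(25, 45),
                 data = data),
            class = "amh_fit")
}

# BFGS with finite-difference gradients can stall in the curved shape-space
# valley of the skew-t likelihood while reporting convergence; alternate
# Nelder-Mead and BFGS passes from the incumbent until no further improvement.
polish_optim <- function(o, fn, reltol) {
  for (k in seq_len(8)) {
    o2 <- tryCatch({
      nm <- stats::optim(o$par, fn, method = "Nelder-Mead",
                         control = list(maxit = 3000, reltol = 1e-10))
      stats::optim(nm$par, fn, method = "BFGS",
                   control = list(maxit = 1000, reltol = reltol))
    }, error = function(e) NULL)
    if (is.null(o2)) break
    gain <- o$value - o2$value
    if (o2$value < o$value) o <- o2
    if (gain < 1e-7) break
  }
  o
}

validate_amh_data <- function(data, need = NULL) {
  data <- tibble::as_tibble(data)
  req <- c("age_years", "amh_ng_ml")
  if (any(c("bmi", "bmi_age") %in% need)) req <- c(req, "bmi")
  if (any(c("smoker", "smoker_age") %in% need)) req <- c(req, "smoker")
  missing_cols <- setdiff(req, names(data))
  if (length(missing_cols)) {
    stop("AMH data is missing columns: ", paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(data$amh_ng_ml) | data$amh_ng_ml <= 0)
  if (length(bad)) {
    stop("non-positive AMH at row(s) ",
         paste(utils::head(bad, 5), collapse = ", "),
         if (length(bad) > 5) " ..." else "",
         ": log(AMH) requires amh_ng_ml > 0")
  }
  if (any(!is.finite(data$age_years) | data$age_years <= 0)) {
    stop("ages must be positive and finite")
  }
  if ("bmi" %in% names(data) && any(stats::na.omit(data$bmi) <= 10)) {
    stop("BMI values must exceed 10 kg/m^2")
  }
  data
}

amh_design <- function(data, extra_terms) {
  age <- data$age_years
  X <- cbind(intercept = 1, age = age, age2 = age^2)
  for (tm in extra_terms) {
    col <- switch(tm,
                  age3 = age^3, age4 = age^4,
                  bmi = data$bmi, smoker = data$smoker,
                  bmi_age = data$bmi * age, smoker_age = data$smoker * age)
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- tm
  }
  X
}

#' Assemble a stage-1 model from known parameters
#'
#' Builds an `amh_fit` object directly from regression coefficients and a
#' residual law, without data. Useful for evaluating the downstream threshold
#' machinery at generating parameters (e.g. in simulation studies) and for
#' reconstructing a fitted model from a serialized parameter set.
#'
#' @param coefs Named numeric vector `c(intercept, age, age2)`.
#' @param scale Stage-1 residual scale (log ng/mL).
#' @param shape_a,shape_b Skew-t shape parameters.
#' @param n Nominal sample size to record (default 0).
#' @return An `amh_fit` object (with `loglik = NA` and no data).
#' @export
amh_fit_from_params <- function(coefs, scale, shape_a, shape_b, n = 0L) {
  stopifnot(length(coefs) == 3, all(is.finite(coefs)))
  names(coefs) <- c("intercept", "age", "age2")
  structure(list(coefficients = coefs,
                 residual = skt_mean_zero(skt_params(0, scale, shape_a, shape_b)),
                 loglik = NA_real_, n = as.integer(n), n_params = 6L,
                 terms = character(), converged = NA,
                 optim_counts = NULL, validity_range = c(25, 45),
                 data = NULL),
            class = "amh_fit")
}

#' Fitted mean of log(AMH) at given ages
#'
#' Only defined for models whose mean depends on age alone (the base
#' quadratic, optionally with cubic/quartic terms).
#'
#' @param fit An `amh_fit`.
#' @param age Vector of ages in years.
#' @return Fitted mean log(AMH).
#' @export
amh_mu <- function(fit, age) {
  stopifnot(inherits(fit, "amh_fit"))
  if (any(fit$terms %in% c("bmi", "smoker", "bmi_age", "smoker_age"))) {
    stop("mean depends on covariates beyond age; age-only curves undefined")
  }
  out <- fit$coefficients[["intercept"]] + fit$coefficients[["age"]] * age +
    fit$coefficients[["age2"]] * age^2
  if ("age3" %in% fit$terms) out <- out + fit$coefficients[["age3"]] * age^3
  if ("age4" %in% fit$terms) out <- out + fit$coefficients[["age4"]] * age^4
  out
}

#' Age at which the fitted mean log(AMH) peaks
#'
#' @param fit An `amh_fit` with a quadratic age mean.
#' @return Age in years (`-c_age / (2 c_age2)`).
#' @export
peak_age <- function(fit) {
  stopifnot(inherits(fit, "amh_fit"))
  -fit$coefficients[["age"]] / (2 * fit$coefficients[["age2"]])
}

#' Likelihood-ratio test between nested skew-t regressions
#'
#' @param full,reduced `amh_fit` objects fitted to the same records, with
#'   `reduced`'s mean terms a subset of `full`'s.
#' @return A one-row tibble with `statistic`, `df`, `p_value`.
#' @examples
#' cfg <- meno_config(seed = 1)
#' d <- simulate_amh_cohort(cfg)
#' lr_test(fit_amh(d, extra_terms = "smoker"), fit_amh(d))
#' @export
lr_test <- function(full, reduced) {
  stopifnot(inherits(full, "amh_fit"), inherits(reduced, "amh_fit"))
  if (!all(reduced$terms %in% full$terms)) {
    stop("models are not nested: reduced terms must be a subset of full terms")
  }
  if (full$n != reduced$n) stop("models were fitted to different numbers of records")
  df <- full$n_params - reduced$n_params
  stat <- max(0, 2 * (full$loglik - reduced$loglik))
  p <- if (df == 0) 1 else stats::pchisq(stat, df, lower.tail = FALSE)
  tibble::tibble(statistic = stat, df = df, p_value = p)
}

#' Age-dependent AMH reference centiles
#'
#' Centile value at `(age, prob)` is
#' `exp(mu(age) + qskt(prob, residual law))`. The default age grid covers
#' 25-45 years, where the quadratic mean is well determined; requesting ages
#' outside the validity range triggers a warning, not suppression.
#'
#' @param fit An `amh_fit` with an age-only mean.
#' @param ages Age grid in years.
#' @param probs Centile probabilities.
#' @return A tibble of class `amh_centiles` with columns `age_years`, `prob`,
#'   `amh_ng_ml`, strictly increasing in `prob` at every age.
#' @export
amh_centiles <- function(fit, ages = seq(25, 45, by = 0.25),
                         probs = c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)) {
  stopifnot(inherits(fit, "amh_fit"), all(probs > 0), all(probs < 1))
  warn_outside_validity(fit, ages)
  grid <- tidyr::expand_grid(age_years = ages, prob = sort(probs))
  grid$amh_ng_ml <- exp(amh_mu(fit, grid$age_years) + qskt(grid$prob, fit$residual))
  class(grid) <- c("amh_centiles", class(grid))
  grid
}

warn_outside_validity <- function(fit, ages) {
  vr <- fit$validity_range
  if (any(ages < vr[1] | ages > vr[2])) {
    warning(sprintf("ages outside the centile validity range %g-%g years; %s",
                    vr[1], vr[2],
                    "the mean is poorly determined there"), call. = FALSE)
  }
}

band_edges <- c(0, 0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95, 1)

#' Locate an AMH measurement within the reference centile bands
#'
#' Returns the half-open centile band `(band_low, band_high]` from the edge
#' set \{0, 5, 10, 25, 50, 75, 90, 95, 100\}% containing the measurement's
#' residual-scale probability `pskt(log(amh) - mu(age))`. A measurement
#' lying exactly on a centile curve belongs to the band whose upper edge is
#' that centile.
#'
#' @param fit An `amh_fit` with an age-only mean.
#' @param age,amh Vectors of ages (years) and AMH levels (ng/mL, positive).
#' @return A tibble with `age_years`, `amh_ng_ml`, `centile_prob`,
#'   `band_low`, `band_high`.
#' @export
amh_band <- function(fit, age, amh) {
  stopifnot(inherits(fit, "amh_fit"))
  if (any(amh <= 0)) stop("AMH must be positive")
  warn_outside_validity(fit, age)
  p <- pskt(log(amh) - amh_mu(fit, age), fit$residual)
  # snap to an edge when numerically on a centile curve (half-open convention)
  for (e in band_edges[c(-1, -length(band_edges))]) {
    p[abs(p - e) < 1e-9] <- e
  }
  idx <- findInterval(p, band_edges, left.open = TRUE)
  idx[p == 0] <- 1
  tibble::tibble(age_years = age, amh_ng_ml = amh, centile_prob = p,
                 band_low = band_edges[idx], band_high = band_edges[idx + 1])
}

#' Chi-square statistic from probability-integral-transform values
#'
#' Bins PIT values into `n_bins` equal-probability cells and returns the
#' Pearson statistic with `df = n_bins - 1 - n_params`.
#'
#' @param u PIT values in (0, 1).
#' @param n_bins Number of equal-probability bins (>= 3).
#' @param n_params Number of estimated parameters to charge against `df`.
#' @return A one-row tibble with `statistic`, `df`, `n_bins`.
#' @export
pit_chisq <- function(u, n_bins, n_params = 0) {
  if (n_bins < 3) stop("`n_bins` must be at least 3")
  if (any(u <= 0 | u >= 1)) stop("PIT values must lie strictly inside (0, 1)")
  expected <- length(u) / n_bins
  counts <- tabulate(findInterval(u, seq(0, 1, length.out = n_bins + 1),
                                  left.open = TRUE, rightmost.closed = TRUE),
                     nbins = n_bins)
  tibble::tibble(statistic = sum((counts - expected)^2 / expected),
                 df = n_bins - 1 - n_params, n_bins = n_bins)
}

#' Residual goodness of fit for the skew-t regression
#'
#' Probability-integral transforms of the residuals under the fitted law,
#' binned into `n_bins` equal-probability cells (default one more bin than
#' observations, so `df = n - n_params`). The PIT values themselves are
#' attached as attribute `"pit"`.
#'
#' @param fit An `amh_fit`.
#' @param data Records to evaluate (default: the fitting data).
#' @param n_bins Number of equal-probability bins.
#' @return A one-row tibble with `statistic`, `df`, `n_bins`.
#' @export
residual_gof <- function(fit, data = fit$data, n_bins = nrow(data) + 1) {
  stopifnot(inherits(fit, "amh_fit"))
  data <- validate_amh_data(data, need = fit$terms)
  X <- amh_design(data, fit$terms)
  resid <- log(data$amh_ng_ml) - drop(X %*% fit$coefficients)
  u <- pskt(resid, fit$residual)
  # extreme residuals can round the integral transform to exactly 0 or 1 in
  # floating point; nudge them inside the open interval before binning
  u <- pmin(pmax(u, 1e-12), 1 - 1e-12)
  out <- pit_chisq(u, n_bins, n_params = fit$n_params)
  attr(out, "pit") <- u
  out
}

#' Kernel-smoothed mean of log(AMH) against age
#'
#' Nadaraya-Watson local mean with a Gaussian kernel, for visual concordance
#' with the quadratic fit; not used in estimation.
#'
#' @param data AMH records (`age_years`, `amh_ng_ml`).
#' @param bandwidth Kernel standard deviation in years (> 0).
#' @param ages Evaluation grid (default: the observed age range).
#' @return A tibble with `age_years` and `log_amh_smooth`.
#' @export
smooth_log_amh <- function(data, bandwidth = 3,
                           ages = seq(min(data$age_years), max(data$age_years),
                                      length.out = 101)) {
  if (bandwidth <= 0) stop("`bandwidth` must be positive")
  data <- validate_amh_data(data)
  if (nrow(data) < 30) stop("need at least 30 records to smooth")
  y <- log(data$amh_ng_ml)
  sm <- vapply(ages, function(a0) {
    w <- stats::dnorm((data$age_years - a0) / bandwidth)
    sum(w * y) / sum(w)
  }, numeric(1))
  tibble::tibble(age_years = ages, log_amh_smooth = sm)
}

#' @export
print.amh_fit <- function(x, ...) {
  cat(sprintf("Skew-t regression of log(AMH) on age  (n = %d, loglik = %.2f)\n",
              x$n, x$loglik))
  print(round(x$coefficients, 5))
  cat(sprintf("residual: scale %.4f, shapes (%.3f, %.3f); peak age %.1f y\n",
              x$residual$scale, x$residual$a, x$residual$b, peak_age(x)))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
tidy.amh_fit <- function(x, ...) {
  tibble::tibble(
    term = c(names(x$coefficients), "residual_scale", "shape_a", "shape_b"),
    estimate = c(unname(x$coefficients), x$residual$scale, x$residual$a,
                 x$residual$b))
}

#' @importFrom generics glance
#' @export
glance.amh_fit <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, n = x$n, n_params = x$n_params,
                 peak_age = peak_age(x), converged = x$converged)
}

#' @importFrom ggplot2 autoplot
#' @export
autoplot.amh_fit <- function(object, smooth_bandwidth = 3, ...) {
  grid <- tibble::tibble(age_years = seq(min(object$data$age_years),
                                         max(object$data$age_years),
                                         length.out = 200))
  grid$fit <- amh_mu(object, grid$age_years)
  sm <- smooth_log_amh(object$data, bandwidth = smooth_bandwidth)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$age_years)) +
    ggplot2::geom_point(ggplot2::aes(y = log(.data$amh_ng_ml)),
                        alpha = 0.4, size = 0.8) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       linewidth = 0.9) +
    ggplot2::geom_line(data = sm, ggplot2::aes(y = .data$log_amh_smooth),
                       linetype = "dashed") +
    ggplot2::labs(x = "Age (years)", y = "log AMH (log ng/mL)",
                  title = "Quadratic skew-t mean (solid) and kernel smooth (dashed)")
}

#' @export
autoplot.amh_centiles <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$age_years,
                                       y = .data$amh_ng_ml,
                                       group = factor(.data$prob),
                                       linetype = factor(.data$prob))) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Age (years)", y = "AMH (ng/mL)", linetype = "Centile",
                  title = "Age-dependent AMH reference centiles")
}
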
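test_that("fit_amh validates its inputs", {
  d <- sim_amh()
  expect_error(fit_amh(d[1:10, ]), "at least 30")
  bad <- d; bad$amh_ng_ml[3] <- -1
  expect_error(fit_amh(bad), "row.* 3")
  expect_error(fit_amh(d, extra_terms = "nope"), "unknown extra_terms")
  expect_error(fit_amh(d[, c("age_years")]), "missing columns")
})

test_that("fitted model recovers the generating structure", {
  af <- fitted_amh()
  cal <- default_cfg()$calibration
  expect_true(af$converged)
  # concave mean peaking near the generating peak of 25 years
  expect_lt(af$coefficients[["age2"]], 0)
  expect_lt(abs(peak_age(af) - 25), 4)
  # fitted mean close to the generating mean over the validity range
  ages <- seq(25, 44, by = 0.5)
  gap <- abs(amh_mu(af, ages) -
               (cal$coefs[1] + cal$coefs[2] * ages + cal$coefs[3] * ages^2))
  expect_lt(stats::median(gap), 0.1)
  # residual law has mean zero
  expect_equal(unname(skt_moments(af$residual)$mean), 0, tolerance = 1e-8)
})

test_that("fit is deterministic and location-equivariant", {
  d <- sim_amh()
  af1 <- fit_amh(d)
  af2 <- fit_amh(d)
  expect_identical(af1$coefficients, af2$coefficients)
  shifted <- d
  shifted$amh_ng_ml <- shifted$amh_ng_ml * exp(1)
  af3 <- fit_amh(shifted)
  # equivariance holds up to optimizer convergence noise
  expect_equal(af3$coefficients[["intercept"]],
               af1$coefficients[["intercept"]] + 1, tolerance = 2e-3)
  expect_equal(af3$coefficients[["age"]], af1$coefficients[["age"]],
               tolerance = 1e-3)
  expect_equal(af3$residual$scale, af1$residual$scale, tolerance = 1e-3)
})

test_that("likelihood at the optimum beats the generating parameters", {
  cal <- default_cfg()$calibration
  res1 <- skt_mean_zero(skt_params(0, cal$scale1, cal$shape_a, cal$shape_b))
  wins <- sapply(1:10, function(i) {
    d <- simulate_amh_cohort(default_cfg(), seed = 300 + i)
    af <- fit_amh(d, n_starts = 2)
    ll_true <- sum(dskt(log(d$amh_ng_ml) - mu_at(cal$coefs, d$age_years),
                        res1, log = TRUE))
    af$loglik >= ll_true
  })
  expect_gte(mean(wins), 0.95)
})

test_that("left-skew direction of the residual law is recovered", {
  cal <- default_cfg()$calibration
  res <- skt_mean_zero(skt_params(0, cal$scale1, a = 2, b = 6))
  hits <- sapply(1:20, function(i) {
    d <- with_seed(400 + i, {
      age <- stats::runif(375, 19, 44)
      mu <- cal$coefs[1] + cal$coefs[2] * age + cal$coefs[3] * age^2
      tibble::tibble(age_years = age, amh_ng_ml = exp(mu + rskt(375, res)))
    })
    # extreme shape pairs visited during optimization can trigger harmless
    # gamma-function underflow warnings
    af <- suppressWarnings(fit_amh(d, n_starts = 2))
    af$residual$a < af$residual$b
  })
  expect_gte(mean(hits), 0.9)
})

test_that("lr_test has the right trivial and error behaviour", {
  af <- fitted_amh()
  same <- lr_test(af, af)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  full <- fit_amh(sim_amh(), extra_terms = "smoker", n_starts = 2)
  out <- lr_test(full, af)
  expect_gte(out$statistic, 0)
  expect_equal(out$df, 1)
  expect_error(lr_test(af, full), "not nested")
  other <- fit_amh(sim_amh()[1:300, ], n_starts = 2)
  expect_error(lr_test(af, other), "different numbers of records")
})

test_that("lr_test has power when the tested term is truly present", {
  rejections <- sapply(1:10, function(i) {
    d <- simulate_amh_cohort(default_cfg(), seed = 500 + i)
    # inject a real smoking effect on log(AMH), then test for it
    d$amh_ng_ml <- d$amh_ng_ml * exp(-0.4 * d$smoker)
    full <- fit_amh(d, extra_terms = "smoker", n_starts = 2)
    reduced <- fit_amh(d, n_starts = 2)
    lr_test(full, reduced)$p_value < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("centile curves match direct recomputation and are monotone", {
  af <- fitted_amh()
  ct <- amh_centiles(af, ages = c(30, 40), probs = c(0.25, 0.5, 0.75))
  direct <- exp(amh_mu(af, ct$age_years) + qskt(ct$prob, af$residual))
  expect_equal(ct$amh_ng_ml, direct, tolerance = 1e-12)
  by_age <- split(ct$amh_ng_ml, ct$age_years)
  for (v in by_age) expect_true(all(diff(v) > 0))
  expect_true(all(ct$amh_ng_ml > 0))
  expect_warning(amh_centiles(af, ages = c(20, 30)), "validity range")
})

test_that("median centile exceeds the mean curve under left skew", {
  af <- true_amh_fit()
  expect_lt(af$residual$a, af$residual$b)  # generating law is left-skewed
  ct <- amh_centiles(af, ages = seq(25, 45, by = 5), probs = 0.5)
  expect_true(all(ct$amh_ng_ml > exp(amh_mu(af, ct$age_years))))
})

test_that("symmetric residual puts the median centile on the mean curve", {
  af <- amh_fit_from_params(default_cfg()$calibration$coefs, 0.6, 3, 3)
  ct <- amh_centiles(af, ages = c(30, 40), probs = 0.5)
  expect_equal(ct$amh_ng_ml, exp(amh_mu(af, ct$age_years)), tolerance = 1e-10)
})

test_that("amh_band agrees with brute-force curve comparison", {
  af <- fitted_amh()
  probs <- c(0.05, 0.10, 0.25, 0.50, 0.75, 0.90, 0.95)
  set.seed(11)
  age <- stats::runif(50, 25, 44)
  amh <- stats::runif(50, 0.05, 10)
  band <- amh_band(af, age, amh)
  for (i in seq_len(50)) {
    curves <- amh_centiles(af, ages = age[i], probs = probs)$amh_ng_ml
    k <- sum(amh[i] > curves + 1e-12)
    edges <- c(0, probs, 1)
    expect_equal(band$band_low[i], edges[k + 1])
    expect_equal(band$band_high[i], edges[k + 2])
  }
})

test_that("a measurement exactly on a centile curve joins the band below it", {
  af <- fitted_amh()
  on_curve <- amh_centiles(af, ages = 30, probs = 0.5)$amh_ng_ml
  b <- amh_band(af, 30, on_curve)
  expect_equal(b$band_low, 0.25)
  expect_equal(b$band_high, 0.5)
  expect_error(amh_band(af, 30, -1), "positive")
})

test_that("residual_gof bins PIT values with sensible df bookkeeping", {
  af <- fitted_amh()
  g <- residual_gof(af)
  expect_equal(g$n_bins, nrow(sim_amh()) + 1)
  expect_equal(g$df, g$n_bins - 1 - af$n_params)
  u <- attr(g, "pit")
  expect_true(all(u > 0 & u < 1))
  g2 <- residual_gof(af, n_bins = 2 * (nrow(sim_amh()) + 1))
  expect_identical(attr(g2, "pit"), u)  # PIT invariant to binning
  expect_error(pit_chisq(u, n_bins = 2), "at least 3")
})

test_that("residual_gof is calibrated under the null and inflated when wrong", {
  af <- true_amh_fit()
  ratios <- sapply(1:40, function(i) {
    d <- with_seed(600 + i, {
      age <- stats::runif(375, 19, 44)
      tibble::tibble(age_years = age,
                     amh_ng_ml = exp(amh_mu(af, age) + rskt(375, af$residual)))
    })
    g <- residual_gof(af, d)
    g$statistic / g$df
  })
  expect_gt(stats::median(ratios), 0.85)
  expect_lt(stats::median(ratios), 1.15)
  # grossly misspecified law inflates the statistic
  wrong <- amh_fit_from_params(default_cfg()$calibration$coefs, 0.2, 2, 40)
  bad <- sapply(1:10, function(i) {
    d <- with_seed(700 + i, {
      age <- stats::runif(375, 19, 44)
      tibble::tibble(age_years = age,
                     amh_ng_ml = exp(amh_mu(af, age) + rskt(375, af$residual)))
    })
    residual_gof(wrong, d)$statistic
  })
  expect_gt(mean(bad > stats::qchisq(0.99, df = 375)), 0.9)
})

test_that("smooth_log_amh obeys its limits and tracks the quadratic fit", {
  d <- sim_amh()
  flat <- d
  flat$amh_ng_ml <- 2
  sm0 <- smooth_log_amh(flat, bandwidth = 3)
  expect_equal(sm0$log_amh_smooth, rep(log(2), nrow(sm0)), tolerance = 1e-12)
  smh <- smooth_log_amh(d, bandwidth = 1e6)
  expect_equal(smh$log_amh_smooth,
               rep(mean(log(d$amh_ng_ml)), nrow(smh)), tolerance = 1e-6)
  expect_error(smooth_log_amh(d, bandwidth = 0), "positive")
  af <- fitted_amh()
  grid <- seq(25, 44, by = 0.5)
  sm <- smooth_log_amh(d, bandwidth = 3, ages = grid)
  expect_lt(max(abs(sm$log_amh_smooth - amh_mu(af, grid))), 0.25)
})

test_that("tidy and glance return the documented tibbles", {
  af <- fitted_amh()
  td <- tidy(af)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("intercept", "age", "age2", "residual_scale",
                    "shape_a", "shape_b") %in% td$term))
  gl <- glance(af)
  expect_equal(gl$n, nrow(sim_amh()))
  expect_true(gl$converged)
  pl <- ggplot2::autoplot(af)
  expect_s3_class(pl, "ggplot")
  pc <- ggplot2::autoplot(amh_centiles(af))
  expect_s3_class(pc, "ggplot")
})
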
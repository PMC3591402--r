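test_that("meno_cdf is a proper distribution function beyond the peak", {
  m <- true_model()
  ages <- seq(36, 64, by = 2)
  p <- meno_cdf(m, ages)
  expect_true(all(diff(p) > 0))
  expect_lt(meno_cdf(m, 30.1), 0.02)
  expect_lt(meno_cdf(m, 30.1), meno_cdf(m, 36))
  expect_gt(meno_cdf(m, 79), 0.999)
  expect_error(meno_cdf(m, 20), "peak age")
  expect_error(meno_pdf(m, 24), "peak age")
  expect_error(meno_cdf(list(), 50), "meno_model")
})

test_that("meno_cdf matches quadrature of meno_pdf", {
  m <- true_model()
  for (y in c(45, 50, 58)) {
    q <- stats::integrate(function(u) meno_pdf(m, u), m$peak_age + 1e-9, y,
                          rel.tol = 1e-10)$value
    expect_equal(meno_cdf(m, y) - meno_cdf(m, m$peak_age + 1e-9), q,
                 tolerance = 1e-6)
  }
  # total mass beyond the peak integrates to 1 minus the sub-peak floor
  total <- stats::integrate(function(u) meno_pdf(m, u), m$peak_age + 1e-9, 80,
                            rel.tol = 1e-10)$value
  expect_equal(total, 1 - meno_cdf(m, m$peak_age + 1e-9), tolerance = 1e-4)
})

test_that("meno_pdf matches a finite-difference derivative and is unimodal-ish", {
  m <- true_model()
  h <- 1e-5
  fd <- (meno_cdf(m, 50 + h) - meno_cdf(m, 50 - h)) / (2 * h)
  expect_equal(meno_pdf(m, 50), fd, tolerance = 1e-6)
  expect_lt(meno_pdf(m, 36), meno_pdf(m, 49.5))
})

test_that("percentiles roundtrip through the cdf and order correctly", {
  m <- true_model()
  pc <- meno_percentiles(m, probs = c(0.1, 0.5, 0.9))
  for (i in seq_len(nrow(pc))) {
    expect_equal(meno_cdf(m, pc$age_years[i], pc$bmi_category[i],
                          pc$smoker[i]),
                 pc$prob[i], tolerance = 1e-8)
  }
  wide <- tidyr::pivot_wider(pc, names_from = "prob",
                             values_from = "age_years")
  expect_true(all(wide$`0.1` < wide$`0.5` & wide$`0.5` < wide$`0.9`))
  # smokers reach every percentile earlier within each BMI category
  for (cat in c("under", "normal", "over", "obese")) {
    s0 <- pc$age_years[pc$bmi_category == cat & pc$smoker == 0]
    s1 <- pc$age_years[pc$bmi_category == cat & pc$smoker == 1]
    expect_true(all(s1 < s0))
  }
  expect_error(meno_percentiles(m, probs = 0), "probs > 0")
})

test_that("BMI ordering of thresholds gives stochastic dominance", {
  m <- true_model()
  ages <- seq(40, 60, by = 5)
  # higher threshold => menopause earlier: under < normal < over at each age
  for (sm in c(0L, 1L)) {
    expect_true(all(meno_cdf(m, ages, "under", sm) >
                      meno_cdf(m, ages, "normal", sm)))
    expect_true(all(meno_cdf(m, ages, "normal", sm) >
                      meno_cdf(m, ages, "over", sm)))
  }
})

test_that("fit_threshold validates data and identifiability", {
  af <- true_amh_fit()
  d <- sim_meno()
  expect_error(fit_threshold(d[1:50, ], af), "at least 100")
  bad <- d; bad$age_menopause_years[2] <- 70
  expect_error(fit_threshold(bad, af), "range \\(35, 65\\)")
  one_smoke <- d[d$smoker == 0, ]
  expect_error(fit_threshold(one_smoke, af), "smoking offset unidentifiable")
  no_obese <- d[d$bmi_category != "obese", ]
  expect_error(fit_threshold(no_obese, af), "obese")
  with_terms <- fit_amh(sim_amh(), extra_terms = "age3", n_starts = 1)
  expect_error(fit_threshold(d, with_terms), "plain quadratic")
})

test_that("stage-2 fit recovers generating parameters with stage 1 at truth", {
  tf <- fixture("tf_truth", fit_threshold(sim_meno(), true_amh_fit()))
  th <- exp(tf$model$log_thresholds)
  expect_lt(abs(th[["normal_nonsmoker"]] - 0.31), 0.05)
  expect_lt(abs(th[["normal_smoker"]] - 0.36), 0.06)
  expect_gt(tf$kappa, 0.55)
  expect_lt(tf$kappa, 0.95)
  expect_true(tf$converged)
  # additive structure: smoker minus non-smoker gap constant across BMI
  gaps <- tf$model$log_thresholds[c(2, 4, 6, 8)] -
    tf$model$log_thresholds[c(1, 3, 5, 7)]
  expect_equal(unname(diff(range(gaps))), 0, tolerance = 1e-10)
})

test_that("fitted loglik beats the generating parameters", {
  tf <- fixture("tf_truth", fit_threshold(sim_meno(), true_amh_fit()))
  m <- true_model()
  d <- sim_meno()
  # window-conditioned log-likelihood of the data at the generating model
  dens <- meno_pdf(m, d$age_menopause_years, d$bmi_category, d$smoker)
  win <- meno_cdf(m, 65, d$bmi_category, d$smoker) -
    meno_cdf(m, 35, d$bmi_category, d$smoker)
  expect_gte(tf$loglik, sum(log(dens / win)))
})

test_that("no-covariate fit sits between the extreme profiles", {
  tf <- fixture("tf_truth", fit_threshold(sim_meno(), true_amh_fit()))
  tf0 <- fit_threshold(sim_meno(), true_amh_fit(), covariates = FALSE)
  expect_equal(tf0$n_params, 2L)
  p0 <- meno_percentiles(tf0, probs = c(0.25, 0.5, 0.75),
                         profiles = tibble::tibble(bmi_category = "normal",
                                                   smoker = 0L))
  pall <- meno_percentiles(tf, probs = c(0.25, 0.5, 0.75))
  for (p in c(0.25, 0.5, 0.75)) {
    rng <- range(pall$age_years[pall$prob == p])
    expect_gt(p0$age_years[p0$prob == p], rng[1])
    expect_lt(p0$age_years[p0$prob == p], rng[2])
  }
})

test_that("interval-censored and joint variants run and stay close", {
  af <- true_amh_fit()
  d <- sim_meno()[1:800, ]
  tf_exact <- fit_threshold(d, af)
  tf_int <- fit_threshold(d, af, censoring = "interval")
  expect_lt(abs(tf_int$alpha - tf_exact$alpha), 0.15)
  expect_error(fit_threshold(d, af, covariates = FALSE, method = "joint"),
               "joint fit requires")
})

test_that("meno_cdf_compare reports the KS gap and refuses tiny strata", {
  m <- true_model()
  d <- sim_meno()
  cmp <- meno_cdf_compare(d, m, "normal", 0L)
  expect_lt(cmp$max_gap, 0.06)
  expect_equal(cmp$n, sum(d$bmi_category == "normal" & d$smoker == 0))
  expect_true(all(c("empirical", "model") %in% names(cmp$curves)))
  # empirical curve ends at 1
  expect_equal(max(cmp$curves$empirical), 1)
  few <- d[d$bmi_category == "normal" & d$smoker == 0, ][1:10, ]
  few$bmi_category <- "under"
  few$smoker <- 1L
  expect_error(meno_cdf_compare(few, m, "under", 1L), "too few")
  # shifting ages inflates the gap
  shifted <- d
  shifted$age_menopause_years <- pmin(shifted$age_menopause_years + 5, 64.9)
  expect_gt(meno_cdf_compare(shifted, m, "normal", 0L)$max_gap, cmp$max_gap)
  expect_s3_class(ggplot2::autoplot(cmp), "ggplot")
})

test_that("bootstrap is seeded, contains the point estimates, and validates", {
  tf <- fit_threshold(sim_meno()[1:600, ], true_amh_fit())
  expect_error(meno_bootstrap(tf, n_boot = 50), "at least 100")
  bs1 <- meno_bootstrap(tf, n_boot = 100, seed = 5, percentile_probs = 0.5)
  bs2 <- meno_bootstrap(tf, n_boot = 100, seed = 5, percentile_probs = 0.5)
  expect_identical(bs1, bs2)
  inside <- bs1$estimate >= bs1$conf.low & bs1$estimate <= bs1$conf.high
  expect_gte(mean(inside), 0.9)
  expect_true(all(c("term", "estimate", "se", "conf.low", "conf.high")
                  %in% names(bs1)))
  expect_true(any(grepl("^threshold_", bs1$term)))
  expect_true(any(grepl("^percentile_", bs1$term)))
  expect_true("kappa" %in% bs1$term)
})

test_that("tidy, glance and print work for threshold fits", {
  tf <- fitted_threshold()
  td <- tidy(tf)
  expect_equal(td$term, c("alpha", "beta_under", "beta_over", "beta_obese",
                          "gamma_smoke", "kappa"))
  gl <- glance(tf)
  expect_equal(gl$n, nrow(sim_meno()))
  expect_output(print(tf), "reference threshold")
})
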
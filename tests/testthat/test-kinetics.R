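test_that("an exactly linear course is recovered with its slope", {
  s <- assay_series(0:10, od600 = 1, conc_uM = 100 - 5 * (0:10))
  fit <- fit_concentration_course(s)
  expect_equal(fit$form, "linear")
  expect_equal(unname(fit$coefficients["slope"]), -5, tolerance = 1e-10)
  expect_equal(instantaneous_rate(fit, c(0, 5, 10)), rep(5, 3))
})

test_that("a constant course yields zero rate everywhere", {
  s <- assay_series(0:10, od600 = 1, conc_uM = rep(80, 11))
  fit <- fit_concentration_course(s)
  expect_equal(instantaneous_rate(fit, 0:10), rep(0, 11))
})

test_that("analytic derivatives agree with central finite differences", {
  h <- 1e-4
  # exponential decline
  t <- seq(0, 10, 0.5)
  fit_e <- fit_concentration_course(
    assay_series(t, od600 = 1, conc_uM = 100 * exp(-0.3 * t)))
  expect_equal(fit_e$form, "exp_offset")
  # sigmoidal decline
  fit_l <- fit_concentration_course(
    assay_series(t, od600 = 1, conc_uM = 100 / (1 + exp((t - 5) / 0.8))))
  expect_equal(fit_l$form, "logistic")
  for (fit in list(fit_e, fit_l)) {
    tg <- seq(0.5, 9.5, 0.25)
    fd <- -(fit$fn(tg + h) - fit$fn(tg - h)) / (2 * h)
    expect_equal(instantaneous_rate(fit, tg), fd, tolerance = 1e-6)
  }
  expect_error(instantaneous_rate(fit_e, 11), "outside")
})

test_that("fitted initial concentration is recovered under noise", {
  c0s <- vapply(1:20, function(s) {
    g <- resting_growth(0.05 / 0.36)
    sim <- simulate_depletion(g, consumption_params(100, km = 20),
                              abiotic_off(), 100,
                              noise_spec(conc_sd = 2, seed = s))
    fit <- fit_concentration_course(apply_detection_limit(sim$series))
    fit$fn(0)
  }, numeric(1))
  expect_lt(abs(median(c0s) - 100) / 100, 0.05)
})

test_that("rate-biomass pairing applies the dry-weight conversion", {
  s <- assay_series(0:10, od600 = 8, conc_uM = 100 - 5 * (0:10),
                    mode = "resting")
  fit <- fit_concentration_course(s)
  pairs <- rate_vs_biomass(fit, s, 0.36)
  expect_equal(pairs$x_dw, rep(8 * 0.36, 11))
  # doubling the conversion doubles biomass and halves the activity
  pairs2 <- rate_vs_biomass(fit, s, 0.72)
  expect_equal(pairs2$x_dw, 2 * pairs$x_dw)
  a1 <- as.numeric(specific_activity(pairs))
  a2 <- as.numeric(specific_activity(pairs2))
  expect_equal(a2, a1 / 2)
})

test_that("the initial linear window covers proportional prefixes only", {
  # perfectly proportional: whole series
  p <- data.frame(x_dw = seq(0.1, 1, 0.1), rate = 50 * seq(0.1, 1, 0.1))
  w <- initial_linear_window(p)
  expect_equal(w$indices, 1:10)
  expect_true(w$proportional)
  # proportional for 5 points, then the substrate runs out and the rate
  # collapses while biomass keeps growing
  p2 <- data.frame(x_dw = 1:9, rate = c(10 * (1:5), 20, 5, 1, 0))
  w2 <- initial_linear_window(p2)
  expect_equal(max(w2$indices), 5)
  # three points only
  p3 <- data.frame(x_dw = 1:3, rate = c(10, 30, 15))
  w3 <- initial_linear_window(p3)
  expect_equal(w3$indices, 1:3)
  expect_false(w3$proportional)
  expect_error(initial_linear_window(p3[1:2, ]), "at least")
})

test_that("specific activity is the origin-constrained slope in umol/gDW/h", {
  p <- data.frame(x_dw = rep(0.05, 6), rate = rep(5, 6))
  expect_equal(as.numeric(specific_activity(p)), 100)
  p0 <- data.frame(x_dw = rep(0.05, 6), rate = rep(0, 6))
  expect_equal(as.numeric(specific_activity(p0)), 0)
})

test_that("below-threshold reporting uses the upper confidence bound strictly", {
  expect_true(classify_below_threshold(0.3, threshold = 1, sd = 0.2)$below)
  expect_equal(classify_below_threshold(0.3, threshold = 1, sd = 0.2)$label,
               "< 1")
  r <- classify_below_threshold(26.9, threshold = 1, sd = 12.2)
  expect_false(r$below)
  expect_equal(classify_below_threshold(1, threshold = 1, sd = 0)$below, FALSE)
})

test_that("stationary-phase losses uncorrelated with biomass are not reported as activity", {
  t <- seq(0, 24, 0.5)
  od <- simulate_growth(growth_params(0.05, 0.6, log(2), lag = 2), t)
  # substrate untouched during growth, slow linear leak from t = 10 h
  conc <- 100 - pmax(0, t - 10) * 1
  s <- assay_series(t, od, conc)
  res <- assay_specific_activity(s)
  expect_true(classify_below_threshold(res, threshold = 1)$below)
})

test_that("specific activity is invariant to expressing time in minutes", {
  g <- resting_growth(0.05 / 0.36)
  sim <- simulate_depletion(g, consumption_params(100, km = 0), abiotic_off(),
                            100)
  res_h <- assay_specific_activity(sim$series)
  s_min <- sim$series
  s_min$time_h <- s_min$time_h * 60
  res_m <- assay_specific_activity(s_min)
  # minute-based activity is in umol/gDW/min
  expect_equal(res_m$specific_activity * 60, res_h$specific_activity,
               tolerance = 1e-6)
})

test_that("fitting refuses fully censored or too-short series", {
  s <- assay_series(0:5, od600 = 1, conc_uM = rep(NA_real_, 6),
                    censored = TRUE)
  expect_error(fit_concentration_course(s), "censored")
  s2 <- assay_series(0:2, od600 = 1, conc_uM = c(100, 90, 80))
  expect_error(fit_concentration_course(s2), "at least 4")
})
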
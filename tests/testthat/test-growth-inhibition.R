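test_that("noise-free growth parameters are recovered within 5%", {
  t <- seq(0, 24, 0.2)
  od <- simulate_growth(growth_params(0.05, 0.6, log(2) / 1.1, lag = 5), t)
  p <- fit_growth_parameters(data.frame(time_h = t, od600 = od))
  expect_lt(abs(p$lag_h - 5) / 5, 0.05)
  expect_lt(abs(p$doubling_time_h - 1.1) / 1.1, 0.05)
  expect_lt(abs(p$od_max - 0.6) / 0.6, 0.05)
  expect_false(p$no_growth)
})

test_that("flat curves are flagged as no growth", {
  t <- seq(0, 24, 0.5)
  p <- fit_growth_parameters(data.frame(time_h = t, od600 = rep(0.05, length(t))))
  expect_true(p$no_growth)
  expect_true(is.na(p$doubling_time_h))
})

test_that("a pure exponential gives its doubling time and ~zero lag", {
  t <- seq(0, 6, 0.1)
  od <- simulate_growth(growth_params(0.05, 1e9, log(2)), t)
  p <- fit_growth_parameters(data.frame(time_h = t, od600 = od))
  expect_equal(p$doubling_time_h, 1, tolerance = 0.02)
  expect_lt(p$lag_h, 0.3)
})

test_that("profiles require a 0 uM reference and enough curves", {
  prof <- simulate_inhibition_profile("insensitive")
  cs <- prof$curves
  expect_error(build_profile(cs[names(cs) != "0"]), "0 uM")
  p <- build_profile(prof)
  expect_s3_class(p, "inhibition_profile")
  expect_error(classify_phenotype(p[1:2, ]), "at least 3")
})

test_that("identical curves at all doses give identical parameters", {
  prof <- simulate_inhibition_profile("insensitive")
  p <- build_profile(prof)
  expect_lt(diff(range(p$od_max)) / mean(p$od_max), 0.02)
  expect_lt(diff(range(p$lag_h)) / mean(p$lag_h), 0.05)
  expect_equal(classify_phenotype(p)$class, "insensitive")
})

test_that("gradual lag/doubling extension with stable capacity is detected", {
  prof <- simulate_inhibition_profile("lag_extension",
                                      noise = noise_spec(od_cv = 0.03,
                                                         seed = 42))
  p <- build_profile(prof)
  # the maximum OD stays put (spread < 10%) while lag and doubling grow
  expect_lt(diff(range(p$od_max)) / p$od_max[p$conc_uM == 0], 0.10)
  expect_gt(p$lag_h[p$conc_uM == 1000] / p$lag_h[p$conc_uM == 0], 1.5)
  expect_equal(classify_phenotype(p)$class, "lag_extension")
})

test_that("complete inhibition takes precedence and records its threshold", {
  prof <- simulate_inhibition_profile("capacity_loss_complete",
                                      noise = noise_spec(od_cv = 0.03,
                                                         seed = 7))
  p <- build_profile(prof)
  expect_true(all(p$no_growth[p$conc_uM >= 500]))
  cls <- classify_phenotype(p)
  expect_equal(cls$class, "complete_inhibition_above_threshold")
  expect_equal(cls$threshold_conc_uM, 500)
})

test_that("capacity loss without full inhibition is classified as such", {
  prof <- simulate_inhibition_profile("capacity_loss_complete",
                                      concentrations = c(0, 50, 100, 200))
  cls <- classify_phenotype(build_profile(prof))
  expect_equal(cls$class, "capacity_loss")
})

test_that("classification is invariant to uniform time rescaling", {
  prof <- simulate_inhibition_profile("lag_extension",
                                      noise = noise_spec(od_cv = 0.02,
                                                         seed = 3))
  p1 <- classify_phenotype(build_profile(prof))$class
  rescaled <- lapply(prof$curves, function(d)
    data.frame(time_h = d$time_h * 60, od600 = d$od600))
  p2 <- classify_phenotype(build_profile(rescaled))$class
  expect_identical(p1, p2)
})
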
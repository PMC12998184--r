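test_that("with no sinks the concentration stays at the effective C0", {
  g <- resting_growth(2)
  sim <- simulate_depletion(g, consumption_params(0, km = 0), abiotic_off(),
                            c_nominal = 100)
  expect_equal(sim$series$conc_uM, rep(100, nrow(g)), tolerance = 1e-7)
})

test_that("zero-order depletion follows the closed form C = C0 - a*X*t", {
  # X_DW = 0.05 g/L, a = 100 umol/gDW/h -> 5 uM/h, exhausted at 20 h
  g <- resting_growth(0.05 / 0.36)
  sim <- simulate_depletion(g, consumption_params(100, km = 0), abiotic_off(),
                            c_nominal = 100)
  t <- sim$series$time_h
  expect_equal(sim$series$conc_uM, pmax(100 - 5 * t, 0), tolerance = 1e-5)
})

test_that("cysteine scavenging sets the effective initial concentration", {
  g <- resting_growth(1, times = 0:5)
  sim <- simulate_depletion(
    g, consumption_params(0, km = 0),
    abiotic_params(cysteine_mM = 1.5,
                   ph_decay_table = data.frame(ph = 7, rate_per_h = 0)),
    c_nominal = 150
  )
  expect_equal(sim$truth$c0_effective, 100)
  expect_error(
    simulate_depletion(g, consumption_params(0),
                       abiotic_params(cysteine_mM = 10), c_nominal = 100),
    "fully-scavenged"
  )
})

test_that("identical noise seeds give identical simulated experiments", {
  g <- resting_growth(1)
  ns <- noise_spec(od_cv = 0.05, conc_sd = 2, seed = 77)
  s1 <- simulate_depletion(g, consumption_params(50), abiotic_off(), 100, ns)
  s2 <- simulate_depletion(g, consumption_params(50), abiotic_off(), 100, ns)
  expect_identical(s1$series, s2$series)
  s3 <- simulate_depletion(g, consumption_params(50), abiotic_off(), 100,
                           noise_spec(od_cv = 0.05, conc_sd = 2, seed = 78))
  expect_false(identical(s1$series$conc_uM, s3$series$conc_uM))
})

test_that("noise-free concentrations are non-negative and non-increasing", {
  set.seed(11)
  for (i in 1:10) {
    gp <- growth_params(0.05, runif(1, 0.3, 2), runif(1, 0.2, 1.5),
                        lag = runif(1, 0, 5))
    sim <- simulate_assay(gp, seq(0, 24, 0.5),
                          consumption_params(runif(1, 0, 500),
                                             km = runif(1, 0, 50)),
                          abiotic_params(cysteine_mM = 1.5),
                          c_nominal = 150)
    conc <- sim$series$conc_uM
    expect_true(all(conc >= 0))
    expect_true(all(diff(conc) <= 1e-7))
  }
})

test_that("mass balance: consumed analyte equals integral of a*X_DW", {
  gp <- growth_params(0.05, 0.8, log(2) / 1.2, lag = 2)
  times <- seq(0, 12, 0.25)
  a <- 60
  sim <- simulate_assay(gp, times, consumption_params(a, km = 0),
                        abiotic_off(), c_nominal = 100)
  fine <- seq(0, 12, 0.001)
  x <- simulate_growth(gp, fine) * 0.36
  cum <- c(0, cumsum(diff(fine) * (head(x, -1) + tail(x, -1)) / 2)) * a
  expected <- pmax(100 - approx(fine, cum, xout = times)$y, 0)
  expect_equal(sim$series$conc_uM, expected, tolerance = 1e-3)
})

test_that("rescaling time to minutes reproduces the hourly series", {
  gp <- growth_params(0.05, 0.8, log(2) / 1.2, lag = 2)
  t_h <- seq(0, 12, 0.25)
  od <- simulate_growth(gp, t_h)
  sim_h <- simulate_depletion(data.frame(time_h = t_h, od600 = od),
                              consumption_params(100, km = 20),
                              abiotic_params(cysteine_mM = 1.5),
                              c_nominal = 150)
  # minute-based run: rates divided by 60
  sim_m <- simulate_depletion(
    data.frame(time_h = t_h * 60, od600 = od),
    consumption_params(100 / 60, km = 20),
    abiotic_params(cysteine_mM = 1.5,
                   ph_decay_table = data.frame(
                     ph = c(5.8, 9), rate_per_h = rep(-log(0.9) / 24 / 60, 2))),
    c_nominal = 150
  )
  expect_equal(sim_m$series$conc_uM, sim_h$series$conc_uM, tolerance = 1e-6)
})
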
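rel_err <- function(x, ref) abs(x - ref) / abs(ref)

test_that("colon dry mass follows volume x density x dry fraction", {
  expect_equal(colon_dry_mass(), 104)
  expect_equal(colon_dry_mass(stool_physiology(wet_volume_ml = 100,
                                               density_g_per_ml = 1,
                                               water_fraction = 0.5)), 50)
  expect_error(stool_physiology(water_fraction = 1), "water_fraction")
})

test_that("taxon cell counts scale with abundance", {
  ec <- taxon_profile("Escherichia coli", 0.008, 10966)
  expect_equal(taxon_cells_per_gds(ec), 2.584e9, tolerance = 0.002)
  expect_equal(taxon_cells_per_gds(taxon_profile("none", 0, 1)), 0)
  expect_equal(taxon_cells_per_gds(taxon_profile("all", 1, 1)), 3.23e11)
})

test_that("the full activity chain reproduces the reference extrapolation", {
  phys <- stool_physiology()
  ec <- activity_chain(taxon_profile("Escherichia coli", 0.008, 10966), phys)
  expect_lt(rel_err(ec$cells_per_gds, 2.58e9), 0.02)
  expect_lt(rel_err(ec$biomass_g_per_gds, 0.00065), 0.02)
  expect_lt(rel_err(ec$dry_stool_activity, 7.1), 0.02)
  expect_lt(rel_err(ec$colon_dry_mass_g, 104), 0.02)
  expect_lt(rel_err(ec$total_activity, 742), 0.02)
  fc <- activity_chain(taxon_profile("feces", 1, 74.4), phys)
  expect_lt(rel_err(fc$biomass_g_per_gds, 0.081), 0.02)
  expect_lt(rel_err(fc$dry_stool_activity, 6.0), 0.02)
  expect_lt(rel_err(fc$total_activity, 624), 0.02)
  # invariant: total = dry-stool activity x colon dry mass
  expect_equal(ec$total_activity,
               ec$dry_stool_activity * ec$colon_dry_mass_g)
  # zero activity propagates
  expect_equal(activity_chain(taxon_profile("x", 0.5, 0))$total_activity, 0)
})

test_that("total activity is linear in abundance, activity and dry mass", {
  base <- activity_chain(taxon_profile("x", 0.01, 100))
  expect_equal(activity_chain(taxon_profile("x", 0.02, 100))$total_activity,
               2 * base$total_activity)
  expect_equal(activity_chain(taxon_profile("x", 0.01, 200))$total_activity,
               2 * base$total_activity)
  phys2 <- stool_physiology(wet_volume_ml = 800)
  expect_equal(activity_chain(taxon_profile("x", 0.01, 100),
                              phys2)$total_activity,
               2 * base$total_activity)
})

test_that("bolus amount and detox time form a consistent capacity argument", {
  expect_equal(bolus_amount(50, 400), 20)
  expect_equal(bolus_amount(0, 400), 0)
  expect_equal(bolus_amount(100, 100), 10)
  tm <- detox_time(20, 742)
  expect_equal(tm, 20 / 742 * 60)
  expect_lt(tm, 2)
  expect_equal(detox_time(0, 742), 0)
  expect_equal(detox_time(20, 371), 2 * tm)
  expect_identical(detox_time(20, 0), Inf)
  # conservation: time x activity = amount
  expect_equal(tm / 60 * 742, 20)
})

test_that("abundance back-estimation inverts the activity ratio", {
  ec <- taxon_profile("Escherichia coli", 0.008, 10966)
  expect_equal(round(back_estimate_abundance(74.4, ec), 1), 0.7)
  expect_equal(back_estimate_abundance(0, ec), 0)
  expect_equal(back_estimate_abundance(10966, ec), 100)
  expect_error(back_estimate_abundance(10, taxon_profile("x", 0.1, 0)),
               "> 0")
})

test_that("mixture activity is the renormalized abundance-weighted mean", {
  expect_equal(mixture_activity(list(taxon_profile("a", 0.3, 42))), 42)
  expect_equal(mixture_activity(list(taxon_profile("a", 0.1, 0),
                                     taxon_profile("b", 0.1, 100))), 50)
  expect_error(mixture_activity(list(taxon_profile("a", 0, 10))), "zero")
  # defined community mixture: same order of magnitude as the measured
  # resting-cell community value (~70 umol/gDW/h)
  tab <- colon_nitrite_activities()
  tab$specific_activity <- ifelse(tab$below_threshold, 0, tab$activity)
  tab$abundance <- tab$abundance_pct / 100
  pred <- mixture_activity(tab)
  expect_gt(pred, 70 / 10)
  expect_lt(pred, 70 * 10)
})
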
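test_that("culture trajectories honour fed-batch structure", {
  traj <- simulate_culture_trajectory(336, 1, seed = 7)
  conc <- traj$concentrations
  expect_true(all(as.matrix(conc) >= 0))
  expect_true(all(diff(traj$time_h) > 0))
  # glucose only increases at feed boundaries
  g <- conc$glucose_g_L
  rising <- which(diff(g) > 1e-12)
  # a feed lands on the first step boundary at or after its scheduled time
  fi <- findInterval(traj$feed_times_h, traj$time_h)
  expect_true(all(rising %in% c(fi, fi - 1)))
  # lactate rises early and declines after the metabolic shift
  expect_gt(max(conc$lactate_g_L), conc$lactate_g_L[1])
  expect_lt(conc$lactate_g_L[length(g)], max(conc$lactate_g_L))
  # glutamine and glutamate stay in the low (sub-g/L) range
  expect_lt(max(conc$glutamine_g_L), 1.2)
  expect_lt(max(conc$glutamate_g_L), 1.0)
})

test_that("degenerate and seeded trajectory contracts hold", {
  t0 <- simulate_culture_trajectory(0, 1, seed = 3)
  expect_identical(t0$time_h, 0)
  expect_identical(nrow(t0$concentrations), 1L)

  a <- simulate_culture_trajectory(120, 1, seed = 11)
  b <- simulate_culture_trajectory(120, 1, seed = 11)
  c <- simulate_culture_trajectory(120, 1, seed = 12)
  expect_identical(a$concentrations, b$concentrations)
  expect_false(identical(a$concentrations, c$concentrations))

  expect_error(simulate_culture_trajectory(10, 1, default_kinetics(mu = -1)),
               ">= 0")
  expect_error(simulate_culture_trajectory(10, 1,
                 kinetics = list(q_glucose = NaN)), "finite")
})

test_that("spectrum generation follows the band-sum formula", {
  prof <- quiet_profile()
  zero <- generate_spectrum(c(glucose = 0, lactate = 0), prof,
                            background = NULL, seed = 1)
  expect_true(all(zero$intensities == 0))

  # linearity: doubling one analyte doubles its additive contribution
  c1 <- generate_spectrum(c(glucose = 5), prof, background = NULL, seed = 1)
  c2 <- generate_spectrum(c(glucose = 10), prof, background = NULL, seed = 1)
  expect_equal(c2$intensities, 2 * c1$intensities, tolerance = 1e-12)
  # and matches direct evaluation of the band sum
  peaks <- default_peak_library()
  direct <- 5 * ramanpls:::eval_bands(c1$wavenumbers, peaks$glucose, 0, 1)
  expect_equal(c1$intensities, direct, tolerance = 1e-12)
})

test_that("native grids have the documented point counts", {
  expect_length(profile_grid(quiet_profile(100, 3425, 1)), 3326)
  expect_length(profile_grid(quiet_profile(100, 4000, 3)), 1301)
})

test_that("unknown analytes and invalid profiles are rejected", {
  expect_error(generate_spectrum(c(sucrose = 1), quiet_profile()), "sucrose")
  expect_error(instrument_profile(100, 3425, 0), "grid_increment")
  expect_error(instrument_profile(500, 3425, 1), "cover 300-3400")
  expect_error(analyte_peak_model("x", data.frame(center = 200, width = 5,
                                                  shape = "gaussian",
                                                  coefficient = 1)),
               "300-3400")
})

test_that("single-analyte variation gives a rank-1 signal matrix", {
  prof <- quiet_profile(100, 4000, 3)
  concs <- seq(1, 10, length.out = 6)
  X <- t(vapply(concs, function(cc) {
    generate_spectrum(c(lactate = cc), prof, background = NULL,
                      seed = 1)$intensities
  }, numeric(1301)))
  sv <- svd(scale(X, center = TRUE, scale = FALSE))$d
  expect_lt(sv[2] / sv[1], 1e-10)
})

test_that("dilution series defaults match the printed design", {
  dil <- generate_dilution_series(seed = 5)
  expect_identical(n_samples(dil), 30L)
  rng <- max(dil$reference$glucose_g_L) - min(dil$reference$glucose_g_L)
  expect_equal(rng, 97)

  one <- generate_dilution_series(levels = 5, replicates = 1, seed = 5)
  expect_identical(n_samples(one), 1L)

  again <- generate_dilution_series(seed = 5)
  expect_identical(dil$intensities, again$intensities)
  expect_error(generate_dilution_series(levels = numeric(0)), "empty")
})

test_that("multi-site generation matches its configuration", {
  specs <- list(list(name = "solo", profile = quiet_profile(), n_batches = 1,
                     spectra_per_batch = 1))
  solo <- generate_multisite_dataset(specs, seed = 1)$solo
  expect_identical(n_samples(solo), 1L)

  sites <- generate_multisite_dataset(tiny_site_specs(), seed = 1)
  expect_identical(vapply(sites, n_samples, integer(1)),
                   c(site1 = 9L, site3 = 9L))
  # different instrument families: different native grid lengths
  expect_false(length(sites$site1$grid) == length(sites$site3$grid))
  # determinism
  again <- generate_multisite_dataset(tiny_site_specs(), seed = 1)
  expect_identical(sites$site1$intensities, again$site1$intensities)
})

test_that("packaged configs load into valid study specifications", {
  desk <- load_synth_config(system.file("extdata", "sites_desk.yaml",
                                        package = "ramanpls"))
  expect_length(desk$site_specs, 4)
  expect_s3_class(desk$site_specs[[1]]$profile, "instrument_profile")
  expect_identical(vapply(desk$site_specs, `[[`, numeric(1), "n_spectra"),
                   c(30, 96, 30, 15))
  dil <- load_synth_config(system.file("extdata", "dilution.yaml",
                                       package = "ramanpls"))
  expect_identical(dil$dilution$levels,
                   c(100, 50, 40, 30, 20, 11, 9, 7, 5, 3))
})

test_that("mmol conversion uses the fixed molar masses", {
  expect_equal(mmol_to_g_per_L(c(glucose = 5))[["glucose"]], 5 * 180.16 / 1000)
  expect_error(mmol_to_g_per_L(c(caffeine = 1)), "caffeine")
})
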
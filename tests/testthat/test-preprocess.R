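grid_1034 <- default_target_grid()

test_that("SG first derivative is exact on low-order polynomials", {
  cfg <- preprocess_config()
  # constant -> zero
  const <- raman_spectrum(grid_1034, rep(7, 1034), sample_id = "const")
  d <- savgol_first_derivative(const, cfg)
  expect_length(d$intensities, 1004)
  expect_lt(max(abs(d$intensities)), 1e-12)

  # linear ramp 5 * nu -> derivative 5 per cm-1 (increment-scaling convention)
  ramp <- raman_spectrum(grid_1034, 5 * grid_1034, sample_id = "ramp")
  expect_lt(max(abs(savgol_first_derivative(ramp, cfg)$intensities - 5)), 1e-9)

  # quadratic a nu^2 + b nu + c -> 2 a nu + b at every retained channel
  a <- 3e-4; b <- -0.2; cc <- 11
  quad <- raman_spectrum(grid_1034, a * grid_1034^2 + b * grid_1034 + cc,
                         sample_id = "quad")
  d <- savgol_first_derivative(quad, cfg)
  expect_lt(max(abs(d$intensities - (2 * a * d$wavenumbers + b))), 1e-9)
})

test_that("SG derivative is linear and trims the window margins", {
  cfg <- preprocess_config()
  set.seed(1)
  x <- rnorm(1034); y <- rnorm(1034)
  sx <- raman_spectrum(grid_1034, x); sy <- raman_spectrum(grid_1034, y)
  sxy <- raman_spectrum(grid_1034, x + y)
  expect_equal(savgol_first_derivative(sxy, cfg)$intensities,
               savgol_first_derivative(sx, cfg)$intensities +
                 savgol_first_derivative(sy, cfg)$intensities,
               tolerance = 1e-10)
  d <- savgol_first_derivative(sx, cfg)
  expect_equal(d$wavenumbers, grid_1034[16:1019])
})

test_that("SG derivative rejects invalid grids", {
  cfg <- preprocess_config()
  irregular <- raman_spectrum(cumsum(runif(100, 0.5, 1.5)), rnorm(100))
  expect_error(savgol_first_derivative(irregular, cfg), "uniform")
  short <- raman_spectrum(1:21, rnorm(21))
  expect_error(savgol_first_derivative(short, cfg), "shorter")
  expect_error(preprocess_config(sg_window = 30), "odd")
  expect_error(preprocess_config(sg_window = 1, sg_polyorder = 2), "odd")
})

test_that("SNV normalizes to zero mean and unit sample SD", {
  expect_equal(snv(c(1, 2, 3)), c(-1, 0, 1))
  set.seed(2)
  for (i in 1:5) {
    x <- rnorm(500, mean = runif(1, -10, 10), sd = runif(1, 0.5, 5))
    z <- snv(x)
    expect_lt(abs(mean(z)), 1e-12)
    expect_lt(abs(sd(z) - 1), 1e-12)
    # affine invariance for positive scale
    expect_equal(snv(3.7 * x + 11), z, tolerance = 1e-10)
  }
  expect_error(snv(rep(2, 10), sample_id = "flat_sample"), "flat_sample")
})

test_that("the preprocessing chain suppresses baseline variation", {
  # same concentrations, wildly different random cubic baselines
  prof_clean <- quiet_profile()
  base <- generate_spectrum(c(glucose = 8, lactate = 2), prof_clean, seed = 1)
  n <- length(base$wavenumbers)
  u <- seq(-1, 1, length.out = n)
  set.seed(9)
  spectra <- lapply(1:6, function(i) {
    drift <- drop(outer(u, 0:3, `^`) %*% rnorm(4, 0, 30))
    raman_spectrum(base$wavenumbers, base$intensities + drift,
                   sample_id = sprintf("s%d", i), batch_id = "b1",
                   site_id = "x")
  })
  ref <- data.frame(sample_id = sprintf("s%d", 1:6), batch_id = "b1",
                    site_id = "x", time_h = 0, glucose_g_L = 8,
                    lactate_g_L = 2, glutamine_g_L = 0, glutamate_g_L = 0)
  raw <- assemble_set(spectra, ref)
  pp <- preprocess_set(raw)
  mean_dist <- function(X) mean(dist(X))
  expect_gt(mean_dist(raw$intensities) / mean_dist(pp$intensities), 100)
})

test_that("preprocessing fingerprints track configuration and grid", {
  dil <- generate_dilution_series(levels = c(10, 3), replicates = 1, seed = 4)
  std <- standardize_set(dil)
  a <- preprocess_set(std, preprocess_config())
  b <- preprocess_set(std, preprocess_config(sg_window = 21))
  expect_false(identical(a$fingerprint, b$fingerprint))
  expect_length(a$grid, 1004)

  no_snv <- preprocess_set(std, preprocess_config(snv = FALSE))
  d1 <- savgol_first_derivative(as_spectrum_list(std)[[1]])
  expect_equal(unname(no_snv$intensities[1, ]), d1$intensities,
               tolerance = 1e-12)
})
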
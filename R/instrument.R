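#' Describe a (synthetic) Raman spectrometer
#'
#' Captures the instrument characteristics the generator varies across sites:
#' the native wavenumber grid, a constant wavenumber offset emulating
#' miscalibration, a peak-broadening factor (optical resolution differences),
#' additive per-channel noise, a smooth random-polynomial baseline, and a
#' per-spectrum multiplicative scatter factor.
#'
#' @param grid_start,grid_end,grid_increment Native grid definition (cm^-1);
#'   increment > 0 and the grid must cover 300-3400 cm^-1 so standardization
#'   never extrapolates.
#' @param wavenumber_offset Constant shift (cm^-1) applied to all band centers
#'   as seen by this instrument (miscalibration stressor; default 0).
#' @param broadening Dimensionless multiplier on band widths (default 1).
#' @param noise_sd Additive i.i.d. Gaussian noise SD per channel (a.u., >= 0).
#' @param baseline_degree Degree of the per-spectrum random polynomial
#'   baseline (default 4).
#' @param baseline_scale SD of the random baseline coefficients (a.u.; 0
#'   disables the baseline).
#' @param scatter_sd SD of the log multiplicative scatter factor per spectrum
#'   (dimensionless; 0 gives factor 1 exactly).
#' @param name Instrument identifier.
#' @return An object of class `instrument_profile`.
#' @export
instrument_profile <- function(grid_start, grid_end, grid_increment,
                               wavenumber_offset = 0, broadening = 1,
                               noise_sd = 0, baseline_degree = 4,
                               baseline_scale = 0, scatter_sd = 0,
                               name = "instrument") {
  assert_scalar_number(grid_increment, "grid_increment", min = 0, allow_zero = FALSE)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(baseline_scale, "baseline_scale", min = 0)
  assert_scalar_number(scatter_sd, "scatter_sd", min = 0)
  assert_scalar_number(broadening, "broadening", min = 0, allow_zero = FALSE)
  assert_scalar_number(wavenumber_offset, "wavenumber_offset")
  if (grid_start > 300 || grid_end < 3400) {
    stop("instrument grid must cover 300-3400 cm-1", call. = FALSE)
  }
  structure(list(grid_start = grid_start, grid_end = grid_end,
                 grid_increment = grid_increment,
                 wavenumber_offset = wavenumber_offset, broadening = broadening,
                 noise_sd = noise_sd, baseline_degree = as.integer(baseline_degree),
                 baseline_scale = baseline_scale, scatter_sd = scatter_sd,
                 name = name),
            class = "instrument_profile")
}

#' Native wavenumber grid of an instrument profile
#'
#' The grid is the largest ladder `start + k * increment` not exceeding the
#' range end, i.e. `floor((end - start)/increment) + 1` points.
#'
#' @param profile An [instrument_profile()].
#' @return Numeric vector of wavenumbers (cm^-1).
#' @export
profile_grid <- function(profile) {
  n <- floor((profile$grid_end - profile$grid_start) / profile$grid_increment) + 1
  profile$grid_start + profile$grid_increment * (seq_len(n) - 1)
}

#' Default instrument profiles for the synthetic study
#'
#' Four calibration-site instruments (two dispersive families: 100-3425 cm^-1
#' at 1 cm^-1 and 100-4000 cm^-1 at 3 cm^-1), a fifth well-calibrated
#' validation instrument used only for the external dilution series, and a
#' sixth unit used for the independent culture run. Offsets are spread around
#' zero (+/- 2 cm^-1) so no single site is centered but the pool is.
#'
#' @return Named list of [instrument_profile()] objects.
#' @export
default_instrument_profiles <- function() {
  list(
    site1 = instrument_profile(100, 3425, 1, wavenumber_offset = 2.0,
                               broadening = 1.00, noise_sd = 0.25,
                               baseline_degree = 3, baseline_scale = 8,
                               scatter_sd = 0.08, name = "disp785_A1"),
    site2 = instrument_profile(100, 3425, 1, wavenumber_offset = -1.2,
                               broadening = 1.06, noise_sd = 0.35,
                               baseline_degree = 3, baseline_scale = 12,
                               scatter_sd = 0.08, name = "disp785_A2"),
    site3 = instrument_profile(100, 4000, 3, wavenumber_offset = 1.0,
                               broadening = 0.97, noise_sd = 0.30,
                               baseline_degree = 3, baseline_scale = 10,
                               scatter_sd = 0.10, name = "compact785_B1"),
    site4 = instrument_profile(100, 4000, 3, wavenumber_offset = -1.6,
                               broadening = 1.08, noise_sd = 0.40,
                               baseline_degree = 3, baseline_scale = 14,
                               scatter_sd = 0.10, name = "compact785_B2"),
    validation = instrument_profile(200, 3600, 2, wavenumber_offset = 0.0,
                                    broadening = 1.02, noise_sd = 0.30,
                                    baseline_degree = 3, baseline_scale = 10,
                                    scatter_sd = 0.06, name = "probe785_V"),
    independent = instrument_profile(150, 3425, 1, wavenumber_offset = 1.0,
                                     broadening = 1.01, noise_sd = 0.30,
                                     baseline_degree = 3, baseline_scale = 10,
                                     scatter_sd = 0.08, name = "disp785_K")
  )
}
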
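#' Generate one synthetic Raman spectrum
#'
#' The spectrum on the instrument's native grid is
#' `m * (sum_a c_a * bands_a(nu) + background(nu)) + baseline(nu) + eps(nu)`,
#' where band sums are evaluated with the instrument's wavenumber offset and
#' broadening, `m` is one log-normal multiplicative scatter draw per spectrum,
#' `baseline` is a random-coefficient polynomial, and `eps` is i.i.d. Gaussian
#' channel noise. The analyte signal is exactly linear in concentration, the
#' modeling assumption behind a linear calibration `Y = XB + E`.
#'
#' @param concentrations Named numeric vector, g/L, >= 0; every name must have
#'   a peak model in `peaks`.
#' @param profile An [instrument_profile()].
#' @param peaks Named list of [analyte_peak_model()]s.
#' @param background Optional [analyte_peak_model()] applied at fixed unit
#'   concentration (see [default_background()]); `NULL` disables it.
#' @param seed Integer seed (scatter, baseline, noise draws).
#' @param sample_id,batch_id,site_id,time_h Metadata stored on the spectrum.
#' @return A [raman_spectrum()].
#' @export
generate_spectrum <- function(concentrations, profile,
                              peaks = default_peak_library(),
                              background = default_background(), seed = 1,
                              sample_id = "sample1", batch_id = NA_character_,
                              site_id = NA_character_, time_h = NA_real_) {
  if (is.null(names(concentrations)) || any(names(concentrations) == "")) {
    stop("concentrations must be a named vector", call. = FALSE)
  }
  if (any(concentrations < 0)) stop("concentrations must be >= 0", call. = FALSE)
  missing <- setdiff(names(concentrations), names(peaks))
  if (length(missing)) {
    stop(sprintf("no peak model for analyte(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  nu <- profile_grid(profile)
  signal <- numeric(length(nu))
  for (a in names(concentrations)) {
    if (concentrations[[a]] > 0) {
      signal <- signal + concentrations[[a]] *
        eval_bands(nu, peaks[[a]], profile$wavenumber_offset, profile$broadening)
    }
  }
  if (!is.null(background)) {
    signal <- signal + eval_bands(nu, background, profile$wavenumber_offset,
                                  profile$broadening)
  }
  set.seed(seed)
  m <- exp(stats::rnorm(1, 0, profile$scatter_sd))
  u <- 2 * (nu - min(nu)) / (max(nu) - min(nu)) - 1
  coefs <- stats::rnorm(profile$baseline_degree + 1, 0, profile$baseline_scale)
  baseline <- drop(outer(u, 0:profile$baseline_degree, `^`) %*% coefs)
  eps <- stats::rnorm(length(nu), 0, profile$noise_sd)
  raman_spectrum(nu, m * signal + baseline + eps,
                 sample_id = sample_id, batch_id = batch_id, site_id = site_id,
                 instrument_id = profile$name, time_h = time_h)
}

#' Generate a dilution-series validation set
#'
#' Emulates an external validation series in which a stock mixture of the
#' four analytes is measured at decreasing dilutions in replicate on a single
#' (held-out) instrument. The `levels` are glucose concentrations; the other
#' analytes are co-diluted in proportion to the stock composition. Defaults
#' follow the printed series: 100, 50, 40, 30, 20, 11, 9, 7, 5, 3 g/L in
#' triplicate (glucose reference range 97 g/L).
#'
#' @param levels Glucose concentrations (g/L), positive.
#' @param replicates Replicates per level (>= 1, default 3).
#' @param profile Instrument profile (default: the held-out validation unit).
#' @param peaks,background As in [generate_spectrum()].
#' @param stock Named stock composition (g/L) fixing co-dilution ratios.
#' @param seed Integer seed.
#' @return A raw [spectra_set()] on the instrument's native grid.
#' @export
generate_dilution_series <- function(levels = c(100, 50, 40, 30, 20, 11, 9, 7, 5, 3),
                                     replicates = 3,
                                     profile = default_instrument_profiles()$validation,
                                     peaks = default_peak_library(),
                                     background = default_background(),
                                     stock = c(glucose = 100, lactate = 20,
                                               glutamine = 8, glutamate = 3),
                                     seed = 1) {
  if (length(levels) == 0) stop("empty level list", call. = FALSE)
  if (any(levels <= 0)) stop("levels must be positive", call. = FALSE)
  if (replicates < 1) stop("replicates must be >= 1", call. = FALSE)
  spectra <- list(); refs <- list(); k <- 0
  for (lv in levels) {
    frac <- lv / stock[["glucose"]]
    conc <- stock * frac
    for (r in seq_len(replicates)) {
      k <- k + 1
      sid <- sprintf("dil_L%g_r%d", lv, r)
      spectra[[k]] <- generate_spectrum(conc, profile, peaks, background,
                                        seed = derive_seed(seed, k),
                                        sample_id = sid, batch_id = "dilution",
                                        site_id = "external", time_h = NA_real_)
      refs[[k]] <- data.frame(sample_id = sid, batch_id = "dilution",
                              site_id = "external", time_h = NA_real_,
                              glucose_g_L = conc[["glucose"]],
                              lactate_g_L = conc[["lactate"]],
                              glutamine_g_L = conc[["glutamine"]],
                              glutamate_g_L = conc[["glutamate"]])
    }
  }
  X <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
  rownames(X) <- vapply(spectra, function(s) s$metadata$sample_id, character(1))
  spectra_set(spectra[[1]]$wavenumbers, X, do.call(rbind, refs))
}

# Distribute a per-site spectrum total as evenly as possible over batches.
distribute_spectra <- function(total, n_batches) {
  base <- total %/% n_batches
  rem <- total - base * n_batches
  base + as.integer(seq_len(n_batches) <= rem)
}

#' Site specifications for the full-scale synthetic corpus
#'
#' Reproduces the scale of the multi-site calibration corpus: 305 spectra in
#' 6 batches (site 1), 958 in 22 (site 2), 295 in 4 (site 3), 148 in 7
#' (site 4) - 1699 spectra in total, on two instrument families.
#'
#' @param profiles Named list of instrument profiles.
#' @return List of per-site spec lists (`name`, `profile`, `n_batches`,
#'   `n_spectra`).
#' @export
site_specs_full <- function(profiles = default_instrument_profiles()) {
  list(
    list(name = "site1", profile = profiles$site1, n_batches = 6, n_spectra = 305),
    list(name = "site2", profile = profiles$site2, n_batches = 22, n_spectra = 958),
    list(name = "site3", profile = profiles$site3, n_batches = 4, n_spectra = 295),
    list(name = "site4", profile = profiles$site4, n_batches = 7, n_spectra = 148)
  )
}

#' Site specifications for the reduced desk-scale corpus
#'
#' Roughly 10% of the full corpus (30/96/30/15 spectra in 5/8/5/5 batches),
#' sized so the complete calibration-transfer experiment runs in well under a
#' minute while keeping enough batches per site that a 70/30 batch split
#' still supports batch-grouped cross-validation on the training side.
#'
#' @inheritParams site_specs_full
#' @return List of per-site spec lists.
#' @export
site_specs_desk <- function(profiles = default_instrument_profiles()) {
  list(
    list(name = "site1", profile = profiles$site1, n_batches = 5, n_spectra = 30),
    list(name = "site2", profile = profiles$site2, n_batches = 8, n_spectra = 96),
    list(name = "site3", profile = profiles$site3, n_batches = 5, n_spectra = 30),
    list(name = "site4", profile = profiles$site4, n_batches = 5, n_spectra = 15)
  )
}

#' Generate the multi-site calibration corpus
#'
#' Each batch is an independently seeded fed-batch trajectory; spectra are
#' emitted at evenly spaced off-line-sampling times over a 14-day run and
#' paired with the trajectory concentrations at those times, so spectra and
#' references arrive already matched.
#'
#' @param site_specs List of site specs (see [site_specs_full()]); each entry
#'   needs `name`, `profile`, `n_batches` and either `n_spectra` (total,
#'   distributed evenly over batches) or `spectra_per_batch`.
#' @param peaks,background As in [generate_spectrum()].
#' @param kinetics Kinetics configuration shared by all batches (per-batch
#'   jitter comes from the seed).
#' @param seed Integer master seed.
#' @param duration_h Batch duration (h) when a batch has more than one
#'   spectrum (default 336 = 14 days).
#' @return Named list of raw [spectra_set()]s, one per site, on their native
#'   instrument grids.
#' @export
generate_multisite_dataset <- function(site_specs = site_specs_desk(),
                                       peaks = default_peak_library(),
                                       background = default_background(),
                                       kinetics = default_kinetics(),
                                       seed = 1, duration_h = 336) {
  out <- list()
  site_idx <- 0
  for (spec in site_specs) {
    site_idx <- site_idx + 1
    if (is.null(spec$n_batches) || spec$n_batches < 1) {
      stop("each site spec needs >= 1 batch", call. = FALSE)
    }
    counts <- if (!is.null(spec$spectra_per_batch)) {
      rep(spec$spectra_per_batch, spec$n_batches)
    } else {
      distribute_spectra(spec$n_spectra, spec$n_batches)
    }
    spectra <- list(); refs <- list(); k <- 0
    for (b in seq_len(spec$n_batches)) {
      bid <- sprintf("%s_b%02d", spec$name, b)
      bseed <- derive_seed(seed, site_idx * 1000 + b)
      nspec <- counts[b]
      dur <- if (nspec > 1) duration_h else 0
      traj <- simulate_culture_trajectory(dur, interval_h = 1,
                                          kinetics = kinetics, seed = bseed,
                                          batch_id = bid, site_id = spec$name)
      sample_times <- round(seq(0, dur, length.out = nspec))
      idx <- findInterval(sample_times, traj$time_h)
      for (s in seq_len(nspec)) {
        k <- k + 1
        conc <- unlist(traj$concentrations[idx[s], ])
        names(conc) <- sub("_g_L$", "", names(conc))
        sid <- sprintf("%s_s%03d", bid, s)
        spectra[[k]] <- generate_spectrum(conc, spec$profile, peaks, background,
                                          seed = derive_seed(bseed, s),
                                          sample_id = sid, batch_id = bid,
                                          site_id = spec$name,
                                          time_h = sample_times[s])
        refs[[k]] <- data.frame(sample_id = sid, batch_id = bid,
                                site_id = spec$name, time_h = sample_times[s],
                                glucose_g_L = conc[["glucose"]],
                                lactate_g_L = conc[["lactate"]],
                                glutamine_g_L = conc[["glutamine"]],
                                glutamate_g_L = conc[["glutamate"]])
      }
    }
    X <- do.call(rbind, lapply(spectra, `[[`, "intensities"))
    rownames(X) <- vapply(spectra, function(s) s$metadata$sample_id, character(1))
    out[[spec$name]] <- spectra_set(spectra[[1]]$wavenumbers, X, do.call(rbind, refs))
  }
  out
}

#' Generate an independent culture-run validation set
#'
#' One fed-batch run on an instrument unit absent from the calibration
#' corpus, with a deliberately narrow, low glucose range (glucose held near a
#' low setpoint) - the regime in which range-relative prediction errors blow
#' up even when absolute errors are modest.
#'
#' @param n_spectra Number of daily samples (default 15).
#' @param profile Instrument profile (default: the independent unit).
#' @param peaks,background,kinetics,seed As elsewhere.
#' @return A raw [spectra_set()] with a single batch.
#' @export
generate_independent_culture <- function(n_spectra = 15,
                                         profile = default_instrument_profiles()$independent,
                                         peaks = default_peak_library(),
                                         background = default_background(),
                                         kinetics = NULL, seed = 1) {
  if (is.null(kinetics)) {
    kinetics <- default_kinetics(glucose0 = 4, glucose_setpoint = 3,
                                 jitter_sd = 0.1)
  }
  specs <- list(list(name = "independent", profile = profile, n_batches = 1,
                     n_spectra = n_spectra))
  generate_multisite_dataset(specs, peaks, background, kinetics, seed = seed)$independent
}

#' Load a synthetic-study configuration file
#'
#' Reads a YAML description of instrument profiles, site specifications and a
#' seed (see the packaged `sites_full.yaml`, `sites_desk.yaml` and
#' `dilution.yaml` under `extdata`).
#'
#' @param path Path to a YAML config file.
#' @return A list with any of `site_specs`, `dilution`, `seed`.
#' @export
load_synth_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(seed = cfg$seed %||% 1)
  as_profile <- function(p) do.call(instrument_profile, p)
  if (!is.null(cfg$sites)) {
    out$site_specs <- lapply(cfg$sites, function(s) {
      list(name = s$name, profile = as_profile(s$profile),
           n_batches = s$n_batches, n_spectra = s$n_spectra,
           spectra_per_batch = s$spectra_per_batch)
    })
  }
  if (!is.null(cfg$dilution)) {
    out$dilution <- list(levels = as.numeric(cfg$dilution$levels),
                         replicates = cfg$dilution$replicates %||% 3,
                         profile = as_profile(cfg$dilution$profile),
                         stock = unlist(cfg$dilution$stock))
  }
  out
}
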
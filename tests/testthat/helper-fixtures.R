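# Shared fixtures, built in code at test time.

# An instrument with no nuisance terms: what the band-sum formula alone gives.
quiet_profile <- function(start = 100, end = 3425, inc = 1, offset = 0,
                          broadening = 1) {
  instrument_profile(start, end, inc, wavenumber_offset = offset,
                     broadening = broadening, noise_sd = 0,
                     baseline_degree = 3, baseline_scale = 0, scatter_sd = 0,
                     name = "quiet")
}

# Tiny two-site corpus for fast integration tests.
tiny_site_specs <- function() {
  p <- default_instrument_profiles()
  list(
    list(name = "site1", profile = p$site1, n_batches = 3, spectra_per_batch = 3),
    list(name = "site3", profile = p$site3, n_batches = 3, spectra_per_batch = 3)
  )
}

# Noiseless rank-2 regression problem: X from two latent factors, y a linear
# combination of the same factors.
two_factor_problem <- function(n = 40, p = 60, seed = 42) {
  set.seed(seed)
  scores <- matrix(rnorm(n * 2), n, 2)
  loadings <- matrix(rnorm(2 * p), 2, p)
  X <- scores %*% loadings
  y <- drop(scores %*% c(2, -1)) + 5
  groups <- rep(sprintf("g%02d", 1:10), length.out = n)
  list(X = X, y = y, groups = groups)
}
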
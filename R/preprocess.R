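#' Preprocessing configuration
#'
#' The default chain is the one selected for calibration: Savitzky-Golay
#' first derivative with a 2nd-order polynomial over a 31-point window,
#' followed by standard normal variate (SNV) scaling per spectrum.
#'
#' @param sg_window Odd window length, > `sg_polyorder` (default 31).
#' @param sg_polyorder Polynomial order of the local fit (default 2); the
#'   derivative order (1) must not exceed it.
#' @param snv Apply SNV after the derivative? (default `TRUE`).
#' @param sd_floor Per-spectrum SD below which SNV refuses to divide.
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(sg_window = 31, sg_polyorder = 2, snv = TRUE,
                              sd_floor = 1e-10) {
  if (sg_window %% 2 != 1 || sg_window <= sg_polyorder) {
    stop("sg_window must be odd and greater than sg_polyorder", call. = FALSE)
  }
  if (sg_polyorder < 1) {
    stop("derivative order 1 requires sg_polyorder >= 1", call. = FALSE)
  }
  structure(list(sg_window = as.integer(sg_window),
                 sg_polyorder = as.integer(sg_polyorder),
                 snv = isTRUE(snv), sd_floor = sd_floor),
            class = "preprocess_config")
}

# Center row of the SG differentiation filter: applied to a window it returns
# the first derivative of the local least-squares fit per *sample step*.
sg_center_coefs <- function(window, polyorder) {
  F <- signal::sgolay(p = polyorder, n = window, m = 1, ts = 1)
  as.numeric(F[(window + 1) / 2, ])
}

check_uniform_grid <- function(grid) {
  d <- diff(grid)
  if (length(d) == 0 || max(abs(d - d[1])) > 1e-8 * abs(d[1])) {
    stop("spectrum must be on a uniform grid", call. = FALSE)
  }
  d[1]
}

# Apply the SG first derivative to the rows of an intensity matrix.
# Output is restricted to interior channels where the full window fits
# (grid trimmed by (window-1)/2 points at each end) and scaled to a
# derivative per cm^-1 by dividing by the grid increment.
sg_derivative_matrix <- function(X, grid, window, polyorder) {
  n <- length(grid)
  if (n < window) stop("spectrum shorter than the SG window", call. = FALSE)
  dx <- check_uniform_grid(grid)
  h <- (window - 1) / 2
  coefs <- sg_center_coefs(window, polyorder)
  n_out <- n - 2 * h
  # banded operator: column j of M holds the filter aligned with output j
  M <- matrix(0, n, n_out)
  for (j in seq_len(n_out)) M[j:(j + window - 1), j] <- coefs
  out <- (X %*% M) / dx
  list(intensities = out, grid = grid[(h + 1):(n - h)])
}

#' Savitzky-Golay first derivative of a spectrum
#'
#' Fits a local least-squares polynomial in a sliding window and returns its
#' analytic first derivative with respect to wavenumber (per cm^-1, i.e. the
#' per-step derivative divided by the grid increment) at each interior point.
#' With a 2nd-order fit the result is exact for quadratic spectra. The grid
#' is trimmed by `(window-1)/2` points at each end; with the 31-point default
#' on the 1034-point target grid, 1004 channels remain.
#'
#' @param spectrum A [raman_spectrum()] on a uniform grid, at least
#'   `sg_window` points long.
#' @param config A [preprocess_config()].
#' @return A [raman_spectrum()] holding the derivative on the trimmed grid.
#' @export
savgol_first_derivative <- function(spectrum, config = preprocess_config()) {
  res <- sg_derivative_matrix(matrix(spectrum$intensities, nrow = 1),
                              spectrum$wavenumbers,
                              config$sg_window, config$sg_polyorder)
  m <- spectrum$metadata
  raman_spectrum(res$grid, drop(res$intensities), sample_id = m$sample_id,
                 batch_id = m$batch_id, site_id = m$site_id,
                 instrument_id = m$instrument_id, time_h = m$time_h)
}

#' Standard normal variate scaling
#'
#' Centers each spectrum and divides by its own sample standard deviation
#' (n - 1 denominator), bringing all spectra to mean 0 and unit SD. Removes
#' per-spectrum offset and multiplicative scatter; invariant under
#' `a * x + b` for `a > 0`.
#'
#' @param x A numeric vector or a [raman_spectrum()].
#' @param sd_floor SD below which the input is treated as constant (error).
#' @param sample_id Identifier used in error messages for bare vectors.
#' @return Same type as `x`, SNV-scaled.
#' @export
snv <- function(x, sd_floor = 1e-10, sample_id = "<vector>") {
  if (inherits(x, "raman_spectrum")) {
    y <- snv(x$intensities, sd_floor, x$metadata$sample_id)
    x$intensities <- y
    return(x)
  }
  s <- sd1(x)
  if (!is.finite(s) || s < sd_floor) {
    stop(sprintf("SNV: spectrum '%s' has standard deviation below %g",
                 sample_id, sd_floor), call. = FALSE)
  }
  (x - mean(x)) / s
}

# Readable fingerprint identifying a preprocessing configuration plus the
# resulting grid; models refuse to predict sets with a different fingerprint.
preprocess_fingerprint <- function(config, grid) {
  sprintf("sg%d-p%d-d1%s|grid:%g:%g:%d",
          config$sg_window, config$sg_polyorder,
          if (config$snv) "-snv" else "", grid[1], grid[length(grid)],
          length(grid))
}

#' Preprocess a grid-aligned spectra set
#'
#' Applies the SG first derivative and (optionally) SNV row-wise and records
#' a preprocessing fingerprint (configuration + resulting grid) on the set so
#' that later predictions can verify compatibility.
#'
#' @param set A standardized [spectra_set()] on a uniform grid.
#' @param config A [preprocess_config()].
#' @return A [spectra_set()] on the trimmed grid with `fingerprint` set.
#' @export
preprocess_set <- function(set, config = preprocess_config()) {
  res <- sg_derivative_matrix(set$intensities, set$grid,
                              config$sg_window, config$sg_polyorder)
  X <- res$intensities
  if (config$snv) {
    for (i in seq_len(nrow(X))) {
      X[i, ] <- tryCatch(
        snv(X[i, ], config$sd_floor, rownames(X)[i]),
        error = function(e) stop(conditionMessage(e), call. = FALSE))
    }
  }
  rownames(X) <- rownames(set$intensities)
  spectra_set(res$grid, X, set$reference,
              fingerprint = preprocess_fingerprint(config, res$grid))
}
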
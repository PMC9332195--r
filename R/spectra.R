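#' Construct a single Raman spectrum
#'
#' A spectrum is one wavenumber grid plus one intensity trace and provenance
#' metadata (sample, batch, site, instrument, acquisition time).
#'
#' @param wavenumbers Numeric vector of Raman shifts (cm^-1), strictly
#'   increasing, all finite.
#' @param intensities Numeric vector of intensities (arbitrary units), same
#'   length as `wavenumbers`, all finite.
#' @param sample_id,batch_id,site_id,instrument_id Character scalars
#'   identifying provenance (defaults `NA`).
#' @param time_h Acquisition time in hours since inoculation (default `NA`).
#' @return An object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumbers, intensities,
                           sample_id = NA_character_, batch_id = NA_character_,
                           site_id = NA_character_, instrument_id = NA_character_,
                           time_h = NA_real_) {
  if (length(wavenumbers) != length(intensities)) {
    stop("wavenumbers and intensities must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 1) stop("empty spectrum", call. = FALSE)
  if (anyNA(wavenumbers) || any(!is.finite(wavenumbers))) {
    stop("non-finite wavenumbers", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop(sprintf("non-finite intensities in sample '%s'", sample_id), call. = FALSE)
  }
  if (length(wavenumbers) > 1 && any(diff(wavenumbers) <= 0)) {
    stop("wavenumber grid must be strictly increasing", call. = FALSE)
  }
  structure(
    list(wavenumbers = as.numeric(wavenumbers),
         intensities = as.numeric(intensities),
         metadata = list(sample_id = sample_id, batch_id = batch_id,
                         site_id = site_id, instrument_id = instrument_id,
                         time_h = time_h)),
    class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  cat(sprintf("<raman_spectrum> %s: %d points, %.0f-%.0f cm-1\n",
              x$metadata$sample_id, length(x$wavenumbers),
              min(x$wavenumbers), max(x$wavenumbers)))
  invisible(x)
}

#' Construct a grid-aligned spectra set
#'
#' A `spectra_set` couples a common wavenumber grid, a samples-by-channels
#' intensity matrix, and a reference table carrying off-line analyte
#' concentrations and batch/site identifiers. Every matrix row must have a
#' matching reference row (joined on `sample_id`); sample ids must be unique.
#'
#' @param grid Common wavenumber grid (cm^-1), strictly increasing.
#' @param intensities Numeric matrix, one row per sample, `length(grid)`
#'   columns; rownames are sample ids.
#' @param reference Data frame with at least `sample_id`, `batch_id`,
#'   `site_id`, `time_h` and one `<analyte>_g_L` column per analyte.
#' @param fingerprint Optional preprocessing fingerprint string (set by
#'   [preprocess_set()]); `NA` for raw sets.
#' @return An object of class `spectra_set`.
#' @export
spectra_set <- function(grid, intensities, reference, fingerprint = NA_character_) {
  intensities <- as.matrix(intensities)
  if (ncol(intensities) != length(grid)) {
    stop("intensity matrix column count must equal grid length", call. = FALSE)
  }
  if (is.null(rownames(intensities))) {
    stop("intensity matrix must carry sample ids as rownames", call. = FALSE)
  }
  if (!is.data.frame(reference) || !"sample_id" %in% names(reference)) {
    stop("reference must be a data frame with a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(reference$sample_id)) {
    dup <- unique(reference$sample_id[duplicated(reference$sample_id)])
    stop(sprintf("duplicated sample id(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  missing_ref <- setdiff(rownames(intensities), reference$sample_id)
  if (length(missing_ref)) {
    stop(sprintf("no reference row for sample(s): %s",
                 paste(missing_ref, collapse = ", ")), call. = FALSE)
  }
  # align reference rows to matrix order
  reference <- reference[match(rownames(intensities), reference$sample_id), ,
                         drop = FALSE]
  rownames(reference) <- NULL
  structure(list(grid = as.numeric(grid), intensities = intensities,
                 reference = reference, fingerprint = fingerprint),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d channels (%.0f-%.0f cm-1)%s\n",
              nrow(x$intensities), length(x$grid), min(x$grid), max(x$grid),
              if (!is.na(x$fingerprint)) paste0(" [", x$fingerprint, "]") else ""))
  invisible(x)
}

#' Number of samples in a spectra set
#' @param set A `spectra_set`.
#' @return Integer sample count.
#' @export
n_samples <- function(set) nrow(set$intensities)

#' Split a spectra set into individual spectra
#'
#' @param set A `spectra_set`.
#' @return A list of [raman_spectrum()] objects, metadata taken from the
#'   reference table.
#' @export
as_spectrum_list <- function(set) {
  lapply(seq_len(nrow(set$intensities)), function(i) {
    ref <- set$reference[i, ]
    raman_spectrum(set$grid, set$intensities[i, ],
                   sample_id = ref$sample_id, batch_id = ref$batch_id,
                   site_id = ref$site_id,
                   instrument_id = ref$instrument_id %||% NA_character_,
                   time_h = ref$time_h)
  })
}

#' Pool several grid-compatible spectra sets
#'
#' Stacks sets row-wise. All sets must share an identical grid and
#' preprocessing fingerprint, and sample ids must stay unique.
#'
#' @param ... `spectra_set` objects (or a single list of them).
#' @return One pooled `spectra_set`.
#' @export
pool_sets <- function(...) {
  sets <- list(...)
  if (length(sets) == 1 && !inherits(sets[[1]], "spectra_set")) sets <- sets[[1]]
  stopifnot(length(sets) >= 1)
  g <- sets[[1]]$grid
  fp <- sets[[1]]$fingerprint
  for (s in sets) {
    if (!isTRUE(all.equal(s$grid, g))) {
      stop("cannot pool sets on different grids; standardize first", call. = FALSE)
    }
    if (!identical(s$fingerprint, fp)) {
      stop("cannot pool sets with different preprocessing fingerprints", call. = FALSE)
    }
  }
  X <- do.call(rbind, lapply(sets, function(s) s$intensities))
  refs <- lapply(sets, function(s) s$reference)
  cols <- Reduce(union, lapply(refs, names))
  refs <- lapply(refs, function(r) { r[setdiff(cols, names(r))] <- NA; r[cols] })
  ref <- do.call(rbind, refs)
  spectra_set(g, X, ref, fingerprint = fp)
}
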
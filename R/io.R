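#' The common target wavenumber grid
#'
#' The spectral range available on all instruments ("least common
#' denominator") runs from 300 cm^-1 up to 3400 cm^-1 in 3 cm^-1 steps. 3400
#' is not reachable from 300 in steps of 3, so the grid is the largest 3 cm^-1
#' ladder from 300 not exceeding 3400: 1034 points ending at 3399 cm^-1.
#'
#' @return Numeric vector `300 + 3k, k = 0..1033`.
#' @export
default_target_grid <- function() seq(300, 3399, by = 3)

#' Write a spectra set to wide CSV
#'
#' Spectra file: first column `wavenumber_cm1`, then one intensity column per
#' sample id. Reference file: `sample_id, batch_id, site_id, time_h,
#' glucose_g_L, lactate_g_L, glutamine_g_L, glutamate_g_L` (missing
#' concentrations as empty cells). UTF-8, `.` decimal separator. The
#' round-trip through [read_spectra()] is lossless to full printed precision.
#'
#' @param set A [spectra_set()].
#' @param spectra_path,reference_path Output CSV paths.
#' @return Invisibly, the two paths.
#' @export
write_spectra <- function(set, spectra_path, reference_path) {
  wide <- data.frame(wavenumber_cm1 = set$grid, t(set$intensities),
                     check.names = FALSE)
  utils::write.csv(wide, spectra_path, row.names = FALSE, quote = FALSE)
  ref_cols <- c("sample_id", "batch_id", "site_id", "time_h", "glucose_g_L",
                "lactate_g_L", "glutamine_g_L", "glutamate_g_L")
  ref <- set$reference
  ref <- ref[intersect(c(ref_cols, names(ref)), names(ref))]
  utils::write.csv(ref, reference_path, row.names = FALSE, quote = FALSE)
  invisible(c(spectra_path, reference_path))
}

#' Read spectra from wide CSV
#'
#' @param path Spectra CSV (schema of [write_spectra()]).
#' @param reference_path Optional reference CSV; when given, batch/site/time
#'   metadata are attached to each spectrum and every spectrum id must have a
#'   reference row.
#' @return A list of [raman_spectrum()] objects. The reference table, if
#'   read, is attached as attribute `"reference"`.
#' @export
read_spectra <- function(path, reference_path = NULL) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  wide <- utils::read.csv(path, check.names = FALSE)
  if (names(wide)[1] != "wavenumber_cm1") {
    stop("first column must be wavenumber_cm1", call. = FALSE)
  }
  ids <- names(wide)[-1]
  if (length(ids) == 0) stop("no sample columns in spectra file", call. = FALSE)
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    stop(sprintf("duplicated sample id column(s): %s", paste(dup, collapse = ", ")),
         call. = FALSE)
  }
  nu <- wide$wavenumber_cm1
  if (anyNA(nu) || any(diff(nu) <= 0)) {
    stop("wavenumber column must be strictly increasing and complete", call. = FALSE)
  }
  ref <- NULL
  if (!is.null(reference_path)) {
    ref <- read_reference(reference_path)
    missing <- setdiff(ids, ref$sample_id)
    if (length(missing)) {
      stop(sprintf("no reference row for sample(s): %s",
                   paste(missing, collapse = ", ")), call. = FALSE)
    }
  }
  spectra <- lapply(ids, function(id) {
    y <- wide[[id]]
    if (all(is.na(y))) {
      stop(sprintf("empty intensity column for sample '%s'", id), call. = FALSE)
    }
    meta <- list(batch_id = NA_character_, site_id = NA_character_,
                 time_h = NA_real_)
    if (!is.null(ref)) {
      r <- ref[ref$sample_id == id, ]
      meta <- list(batch_id = as.character(r$batch_id),
                   site_id = as.character(r$site_id), time_h = r$time_h)
    }
    raman_spectrum(nu, y, sample_id = id, batch_id = meta$batch_id,
                   site_id = meta$site_id, time_h = meta$time_h)
  })
  if (!is.null(ref)) attr(spectra, "reference") <- ref
  spectra
}

#' Read a reference-concentration table
#'
#' @param path Reference CSV with `sample_id` plus batch/site/time and
#'   `<analyte>_g_L` columns; empty concentration cells become `NA` (the
#'   sample is then excluded from that analyte's model).
#' @return A data frame.
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  ref <- utils::read.csv(path)
  if (!"sample_id" %in% names(ref)) {
    stop("reference file needs a sample_id column", call. = FALSE)
  }
  if (anyDuplicated(ref$sample_id)) {
    dup <- unique(ref$sample_id[duplicated(ref$sample_id)])
    stop(sprintf("duplicated sample id(s) in reference: %s",
                 paste(dup, collapse = ", ")), call. = FALSE)
  }
  ref$sample_id <- as.character(ref$sample_id)
  ref
}

#' Standardize one spectrum onto a target grid
#'
#' Cubic-spline interpolation of the intensities at the target nodes, so that
#' spectra from heterogeneous instruments become column-compatible - they are
#' recalculated as if acquired on the same spectrometer. Interpolation only:
#' any target node outside the source span is an error, never extrapolated.
#' The spline is exact at the source nodes and reproduces cubic polynomials
#' to machine precision.
#'
#' @param spectrum A [raman_spectrum()].
#' @param target_grid Target wavenumbers (default [default_target_grid()]).
#' @return A [raman_spectrum()] on `target_grid`, metadata preserved.
#' @export
standardize_grid <- function(spectrum, target_grid = default_target_grid()) {
  src <- spectrum$wavenumbers
  if (min(target_grid) < min(src) || max(target_grid) > max(src)) {
    stop(sprintf(
      "target grid [%g, %g] exceeds source span [%g, %g] for sample '%s': refusing to extrapolate",
      min(target_grid), max(target_grid), min(src), max(src),
      spectrum$metadata$sample_id), call. = FALSE)
  }
  f <- stats::splinefun(src, spectrum$intensities, method = "fmm")
  m <- spectrum$metadata
  raman_spectrum(target_grid, f(target_grid), sample_id = m$sample_id,
                 batch_id = m$batch_id, site_id = m$site_id,
                 instrument_id = m$instrument_id, time_h = m$time_h)
}

#' Standardize and stack spectra into one grid-aligned set
#'
#' All spectra are spline-standardized onto the common grid, stacked into one
#' matrix and joined to the reference table on sample id. Reference rows
#' without a spectrum are allowed (ignored with a warning); spectra without a
#' reference row are an error.
#'
#' @param spectra Non-empty list of [raman_spectrum()] objects.
#' @param reference Reference data frame (see [read_reference()]).
#' @param target_grid Common grid (default [default_target_grid()]).
#' @return A [spectra_set()] on `target_grid`.
#' @export
assemble_set <- function(spectra, reference, target_grid = default_target_grid()) {
  if (length(spectra) == 0) stop("empty spectrum list", call. = FALSE)
  ids <- vapply(spectra, function(s) s$metadata$sample_id, character(1))
  missing <- setdiff(ids, reference$sample_id)
  if (length(missing)) {
    stop(sprintf("no reference row for sample(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  extra <- setdiff(reference$sample_id, ids)
  if (length(extra)) {
    warning(sprintf("%d reference id(s) without spectra ignored (e.g. %s)",
                    length(extra), extra[1]), call. = FALSE)
  }
  std <- lapply(spectra, standardize_grid, target_grid = target_grid)
  X <- do.call(rbind, lapply(std, `[[`, "intensities"))
  rownames(X) <- ids
  spectra_set(target_grid, X, reference[reference$sample_id %in% ids, ,
                                        drop = FALSE])
}

#' Standardize a whole raw set onto a target grid
#'
#' Convenience wrapper: splits a set into spectra, standardizes each and
#' reassembles with the same reference table.
#'
#' @param set A raw [spectra_set()] on a native instrument grid.
#' @param target_grid Target grid (default [default_target_grid()]).
#' @return A [spectra_set()] on `target_grid`.
#' @export
standardize_set <- function(set, target_grid = default_target_grid()) {
  assemble_set(as_spectrum_list(set), set$reference, target_grid)
}
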
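#' Define a stylized Raman band model for one analyte
#'
#' Each analyte is represented by a small set of bands; a band contributes
#' `coefficient * shape((nu - center)/width)` arbitrary units per g/L of the
#' analyte. Shapes are Gaussian (`exp(-0.5 z^2)`) or Lorentzian
#' (`1/(1 + z^2)`). The bands are deliberately stylized, not spectroscopically
#' curated: they exist to give the synthetic corpus the overlapping,
#' concentration-linear structure a multivariate calibration needs.
#'
#' @param analyte Analyte name (e.g. `"glucose"`).
#' @param bands Data frame with columns `center` (cm^-1, inside 300-3400),
#'   `width` (cm^-1, > 0), `shape` (`"gaussian"` or `"lorentzian"`) and
#'   `coefficient` (a.u. per g/L, >= 0).
#' @return An object of class `analyte_peak_model`.
#' @export
analyte_peak_model <- function(analyte, bands) {
  bands <- as.data.frame(bands)
  needed <- c("center", "width", "shape", "coefficient")
  if (!all(needed %in% names(bands))) {
    stop("bands need columns center, width, shape, coefficient", call. = FALSE)
  }
  if (nrow(bands) < 1) stop("at least one band per analyte", call. = FALSE)
  if (any(bands$center < 300 | bands$center > 3400)) {
    stop("band centers must lie within 300-3400 cm-1", call. = FALSE)
  }
  if (any(bands$width <= 0)) stop("band widths must be > 0", call. = FALSE)
  if (any(bands$coefficient < 0)) {
    stop("intensity coefficients must be >= 0", call. = FALSE)
  }
  if (!all(bands$shape %in% c("gaussian", "lorentzian"))) {
    stop("shape must be 'gaussian' or 'lorentzian'", call. = FALSE)
  }
  structure(list(analyte = analyte, bands = bands), class = "analyte_peak_model")
}

# Evaluate the band sum of one peak model on a grid, with an instrument
# wavenumber offset (miscalibration) and peak-broadening factor applied.
eval_bands <- function(nu, model, offset = 0, broadening = 1) {
  out <- numeric(length(nu))
  b <- model$bands
  for (i in seq_len(nrow(b))) {
    z <- (nu - b$center[i] - offset) / (b$width[i] * broadening)
    out <- out + b$coefficient[i] *
      if (b$shape[i] == "gaussian") exp(-0.5 * z^2) else 1 / (1 + z^2)
  }
  out
}

#' Default stylized peak library for the four monitored metabolites
#'
#' Glucose, lactate and glutamine carry 4 bands each with partially
#' overlapping centers (so no single channel resolves one analyte and the
#' regression must be multivariate). Glutamate's coefficients are roughly
#' 20-fold smaller: it is deliberately the weak, hard-to-calibrate analyte.
#'
#' @return Named list of [analyte_peak_model()] objects.
#' @export
default_peak_library <- function() {
  list(
    glucose = analyte_peak_model("glucose", data.frame(
      center = c(911, 1060, 1125, 1365),
      width = c(18, 16, 14, 20),
      shape = c("gaussian", "gaussian", "lorentzian", "gaussian"),
      coefficient = c(0.9, 1.2, 1.0, 0.6))),
    lactate = analyte_peak_model("lactate", data.frame(
      center = c(830, 1045, 1090, 1455),
      width = c(16, 15, 18, 22),
      shape = c("gaussian", "gaussian", "lorentzian", "gaussian"),
      coefficient = c(1.0, 1.1, 0.8, 0.5))),
    glutamine = analyte_peak_model("glutamine", data.frame(
      center = c(880, 1100, 1410, 1670),
      width = c(18, 20, 18, 24),
      shape = c("gaussian", "gaussian", "lorentzian", "gaussian"),
      coefficient = c(2.7, 2.1, 2.4, 1.8))),
    glutamate = analyte_peak_model("glutamate", data.frame(
      center = c(860, 1350, 1615),
      width = c(18, 20, 22),
      shape = c("gaussian", "gaussian", "lorentzian"),
      coefficient = c(0.05, 0.045, 0.04)))
  )
}

#' Default water/medium background component
#'
#' A fixed pseudo-component added to every synthetic spectrum: broad water
#' bands plus a few sharper medium bands. In culture Raman the aqueous matrix
#' dominates the signal; keeping a large constant background makes the
#' per-spectrum SNV scaling approximately concentration-independent, so the
#' analyte signal stays effectively linear after preprocessing.
#'
#' @return An [analyte_peak_model()] named `"background"` whose coefficients
#'   are absolute intensities (it is applied at fixed unit concentration).
#' @export
default_background <- function() {
  analyte_peak_model("background", data.frame(
    center = c(440, 790, 1003, 1450, 1640, 2130, 2940, 3230),
    width = c(80, 120, 12, 30, 45, 90, 60, 140),
    shape = c("gaussian", "gaussian", "gaussian", "gaussian",
              "gaussian", "gaussian", "gaussian", "gaussian"),
    coefficient = c(200, 140, 90, 70, 250, 60, 220, 350)))
}

#' Molar masses used to convert mmol/L inputs to g/L
#'
#' @return Named numeric vector, g/mol.
#' @export
molar_masses <- function() {
  c(glucose = 180.16, lactate = 90.08, glutamine = 146.15, glutamate = 147.13)
}

#' Convert mmol/L to g/L for the supported analytes
#' @param mmol Named numeric vector of concentrations in mmol/L.
#' @return Named numeric vector in g/L.
#' @export
mmol_to_g_per_L <- function(mmol) {
  mm <- molar_masses()
  unknown <- setdiff(names(mmol), names(mm))
  if (length(unknown)) {
    stop(sprintf("no molar mass for: %s", paste(unknown, collapse = ", ")),
         call. = FALSE)
  }
  mmol * mm[names(mmol)] / 1000
}
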
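#' Root mean square error
#'
#' `sqrt(sum((y_hat - y)^2) / N)`, in the response's own units (g/L here).
#'
#' @param predicted,reference Equal-length, non-empty numeric vectors.
#' @return Non-negative scalar.
#' @export
rmse <- function(predicted, reference) {
  if (length(predicted) == 0 || length(predicted) != length(reference)) {
    stop("predicted and reference must be equal-length and non-empty", call. = FALSE)
  }
  sqrt(mean((predicted - reference)^2))
}

#' SEC / SEP as percent of the reference range
#'
#' `100 * RMSE / Yrange` where `Yrange` is the highest minus the smallest
#' reference value. The same formula scores calibration (SEC) and prediction
#' (SEP) sets; only the role label differs. Below 5% is conventionally
#' considered very good in bioprocess monitoring, above 10% too high.
#'
#' @param rmse_value RMSE in the reference units.
#' @param reference Reference values whose range normalizes the error.
#' @return Percentage (scalar).
#' @export
sep_percent <- function(rmse_value, reference) {
  yrange <- max(reference) - min(reference)
  if (yrange <= 0) {
    stop("reference range is zero; SEP% undefined", call. = FALSE)
  }
  100 * rmse_value / yrange
}

#' Coefficient of determination
#'
#' `1 - SS_res / SS_tot`: the fraction of reference variability captured by
#' the predictions. Can be negative for worse-than-mean predictions. The
#' squared Pearson correlation is available as an alternative definition for
#' cross-checking.
#'
#' @param predicted,reference Numeric vectors; the reference must not be
#'   constant.
#' @param method `"determination"` (default) or `"pearson"` (squared
#'   correlation).
#' @return Dimensionless scalar (<= 1 for `"determination"`).
#' @export
r_squared <- function(predicted, reference,
                      method = c("determination", "pearson")) {
  method <- match.arg(method)
  if (sd1(reference) == 0) stop("constant reference; R^2 undefined", call. = FALSE)
  if (method == "pearson") {
    return(stats::cor(predicted, reference)^2)
  }
  1 - sum((reference - predicted)^2) / sum((reference - mean(reference))^2)
}

#' Scale values to the 0-1 range (for reporting only)
#'
#' `(v - min) / (max - min)`; the scale parameters are returned so the
#' transform can be inverted. Used to report predictions without disclosing
#' absolute concentrations - never inside model fitting. Range-relative
#' errors (SEP%) are identical on scaled and raw values.
#'
#' @param values Numeric vector with a positive range.
#' @return List with `scaled`, `min`, `max`.
#' @export
minmax_scale <- function(values) {
  lo <- min(values); hi <- max(values)
  if (hi - lo <= 0) stop("range is zero; cannot scale", call. = FALSE)
  list(scaled = (values - lo) / (hi - lo), min = lo, max = hi)
}

#' Invert a 0-1 scaling
#' @param scaled Scaled values.
#' @param params List with `min` and `max` (from [minmax_scale()]).
#' @return Original-scale values.
#' @export
minmax_invert <- function(scaled, params) {
  scaled * (params$max - params$min) + params$min
}

#' Build one evaluation-report row
#'
#' Computes RMSE, R-squared, SEP% (or SEC% - identical formula, role is
#' metadata), the reference range and a conventional quality annotation
#' (`"very good"` < 5%, `"acceptable"` 5-10%, `"too high"` > 10%).
#'
#' @param analyte Analyte name.
#' @param predicted,reference Prediction and reference vectors (g/L).
#' @param role `"calibration"`, `"test"`, `"external"` or `"independent"`.
#' @param condition Label for the calibration condition (e.g. `"pooled"`,
#'   `"site1"`).
#' @return One-row data frame.
#' @export
evaluation_report <- function(analyte, predicted, reference,
                              role = c("calibration", "test", "external",
                                       "independent"),
                              condition = "pooled") {
  role <- match.arg(role)
  e <- rmse(predicted, reference)
  sep <- sep_percent(e, reference)
  data.frame(
    analyte = analyte, condition = condition, role = role,
    n = length(reference), rmse_g_L = e,
    r_squared = r_squared(predicted, reference),
    sep_percent = sep, yrange_g_L = max(reference) - min(reference),
    quality = if (sep < 5) "very good" else if (sep <= 10) "acceptable" else "too high",
    stringsAsFactors = FALSE)
}

#' Verify Eq.-2 self-consistency of a report
#'
#' Recomputes `sep_percent == 100 * rmse / yrange` for every row.
#'
#' @param report Data frame of [evaluation_report()] rows.
#' @param tol Absolute tolerance (default exact up to floating-point noise).
#' @return `TRUE` (invisibly) or an error naming the offending rows.
#' @export
check_report_consistency <- function(report, tol = 1e-12) {
  bad <- which(abs(report$sep_percent -
                     100 * report$rmse_g_L / report$yrange_g_L) > tol)
  if (length(bad)) {
    stop(sprintf("SEP%% inconsistent with RMSE/Yrange in row(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  invisible(TRUE)
}
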
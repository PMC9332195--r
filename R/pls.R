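#' Cross-validation configuration
#'
#' @param folds Number of CV folds (>= 2, default 10). When grouping is
#'   enabled the folds are formed over groups (whole batches stay together).
#' @param group_by Reference column holding the grouping key (default
#'   `"batch_id"`; `NULL` disables grouping and folds over samples).
#' @param max_lv Maximum latent-variable count to scan (default 20; capped at
#'   what the training folds and channel count support).
#' @param tolerance Relative tolerance for the parsimonious LV selection rule
#'   (default 0.01: smallest LV within 1% of the curve minimum).
#' @param seed Integer seed for the fold assignment.
#' @return An object of class `cv_config`.
#' @export
cv_config <- function(folds = 10, group_by = "batch_id", max_lv = 20,
                      tolerance = 0.01, seed = 1) {
  if (folds < 2) stop("folds must be >= 2", call. = FALSE)
  if (max_lv < 1) stop("max_lv must be >= 1", call. = FALSE)
  structure(list(folds = as.integer(folds), group_by = group_by,
                 max_lv = as.integer(max_lv), tolerance = tolerance,
                 seed = seed),
            class = "cv_config")
}

# NIPALS PLS1 core on centered data. Deflates X only; y-loadings q are
# computed against the running scores. Returns weights W, X-loadings P,
# y-loadings q, and the number of components actually extracted (may stop
# early when X is exhausted, i.e. the data rank is reached).
nipals_pls1 <- function(Xc, yc, n_lv, tol = 1e-10) {
  n <- nrow(Xc); p <- ncol(Xc)
  W <- matrix(0, p, n_lv); P <- matrix(0, p, n_lv); q <- numeric(n_lv)
  x_norm0 <- sqrt(sum(Xc^2))
  y_norm <- sqrt(sum(yc^2))
  a <- 0
  for (k in seq_len(n_lv)) {
    w <- crossprod(Xc, yc)                       # p x 1
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn <= tol * max(x_norm0 * y_norm, .Machine$double.xmin)) break
    w <- w / wn
    t <- Xc %*% w
    tt <- sum(t^2)
    if (tt <= (tol * x_norm0)^2) break
    p_k <- crossprod(Xc, t) / tt
    q_k <- sum(yc * t) / tt
    Xc <- Xc - tcrossprod(t, p_k)
    W[, k] <- w; P[, k] <- p_k; q[k] <- q_k
    a <- k
  }
  list(W = W[, seq_len(max(a, 1)), drop = FALSE],
       P = P[, seq_len(max(a, 1)), drop = FALSE],
       q = q[seq_len(max(a, 1))], n_extracted = a)
}

# Regression coefficient vector for the first `a` components:
# B = W (P'W)^-1 q  (the standard PLS1 closed form).
pls_coefficients <- function(fit, a) {
  W <- fit$W[, 1:a, drop = FALSE]
  P <- fit$P[, 1:a, drop = FALSE]
  q <- fit$q[1:a]
  drop(W %*% solve(crossprod(P, W), q))
}

#' Fit a PLS1 regression model by NIPALS
#'
#' Links a preprocessed spectral matrix to one analyte's concentrations via
#' the linear model `Y = XB + E`. X is mean-centered internally (no
#' channel-wise variance scaling: SNV already normalizes scale); y is
#' centered. Components are extracted one at a time with X-deflation; the
#' coefficient vector for the retained count is `B = W (P'W)^-1 q`.
#'
#' @param X Numeric matrix (samples x channels), finite.
#' @param y Numeric response vector (g/L), finite, non-constant.
#' @param n_lv Number of latent variables to retain (>= 1; requesting more
#'   components than the data rank supports is an error).
#' @param analyte Optional analyte name stored on the model.
#' @param fingerprint,grid Optional preprocessing fingerprint and channel
#'   grid stored for later compatibility checks (filled automatically by
#'   [fit_analyte_model()]).
#' @param rmsecv RMSECV curve to store, if available.
#' @return An object of class `pls_model`.
#' @export
fit_pls <- function(X, y, n_lv, analyte = NA_character_,
                    fingerprint = NA_character_, grid = NULL, rmsecv = NULL) {
  X <- as.matrix(X)
  if (!all(is.finite(X)) || !all(is.finite(y))) {
    stop("X and y must be finite", call. = FALSE)
  }
  if (nrow(X) != length(y)) stop("nrow(X) must equal length(y)", call. = FALSE)
  if (nrow(X) < n_lv + 1) {
    stop("need at least n_lv + 1 samples", call. = FALSE)
  }
  if (sd1(y) == 0) stop("zero-variance response", call. = FALSE)
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  fit <- nipals_pls1(sweep(X, 2, x_mean), y - y_mean, n_lv)
  if (fit$n_extracted < n_lv) {
    stop(sprintf("requested %d latent variables but X supports only %d",
                 n_lv, fit$n_extracted), call. = FALSE)
  }
  structure(list(analyte = analyte, x_mean = x_mean, y_mean = y_mean,
                 W = fit$W, P = fit$P, q = fit$q,
                 coefficients = pls_coefficients(fit, n_lv),
                 n_lv = as.integer(n_lv), rmsecv = rmsecv,
                 fingerprint = fingerprint, grid = grid),
            class = "pls_model")
}

#' @export
print.pls_model <- function(x, ...) {
  cat(sprintf("<pls_model> %s: %d LV, %d channels\n",
              x$analyte, x$n_lv, length(x$coefficients)))
  invisible(x)
}

#' Predict concentrations from a fitted PLS model
#'
#' `y_hat = (x - x_mean) . B + y_mean` per sample. When `newdata` is a
#' [spectra_set()], its preprocessing fingerprint and grid must match those
#' stored on the model - applying a calibration to spectra preprocessed
#' differently (or on another grid) is the classic transferability pitfall
#' and is refused rather than silently computed.
#'
#' @param object A [fit_pls()] model.
#' @param newdata A preprocessed [spectra_set()] or a bare numeric matrix
#'   (matrix input skips the fingerprint check but not the dimension check).
#' @param ... Unused.
#' @return Named numeric vector of predictions (g/L).
#' @export
predict.pls_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_set")) {
    if (!is.na(object$fingerprint) &&
        !identical(object$fingerprint, newdata$fingerprint)) {
      stop(sprintf(
        "preprocessing fingerprint mismatch: model '%s' vs data '%s'",
        object$fingerprint, newdata$fingerprint), call. = FALSE)
    }
    if (!is.null(object$grid) && !isTRUE(all.equal(object$grid, newdata$grid))) {
      stop("grid mismatch between model and data", call. = FALSE)
    }
    X <- newdata$intensities
  } else {
    X <- as.matrix(newdata)
  }
  if (ncol(X) != length(object$coefficients)) {
    stop(sprintf("channel count mismatch: model has %d, data has %d",
                 length(object$coefficients), ncol(X)), call. = FALSE)
  }
  drop(sweep(X, 2, object$x_mean) %*% object$coefficients) + object$y_mean
}

# Assign groups to folds, balancing spectra counts: largest group first into
# the currently lightest fold, after a seeded shuffle to break ties randomly.
assign_folds <- function(group_sizes, folds, seed) {
  set.seed(seed)
  groups <- names(group_sizes)
  ord <- sample(length(groups))
  groups <- groups[ord]; sizes <- group_sizes[ord]
  ord2 <- order(sizes, decreasing = TRUE)
  fold_of <- integer(length(groups)); names(fold_of) <- groups
  load <- numeric(folds)
  for (i in ord2) {
    f <- which.min(load)
    fold_of[i] <- f
    load[f] <- load[f] + sizes[i]
  }
  fold_of
}

#' Cross-validated RMSECV curve over latent-variable counts
#'
#' Grouped k-fold cross-validation: all spectra of a batch stay in the same
#' fold, so serially correlated spectra never straddle the train/validation
#' boundary. For each LV count, out-of-fold predictions are pooled and scored
#' with the root-mean-square error. When the training data run out of rank
#' before `max_lv`, the curve is padded with its last value (extra components
#' cannot be extracted and would not change predictions).
#'
#' @param X Preprocessed matrix (samples x channels).
#' @param y Response vector.
#' @param groups Grouping vector (batch ids), one per sample; `NULL` treats
#'   every sample as its own group.
#' @param cv A [cv_config()].
#' @return Numeric vector: RMSECV at LV counts `1..max_lv` (attribute
#'   `"n_lv_effective"` gives the largest honestly estimated count).
#' @export
cross_validate <- function(X, y, groups = NULL, cv = cv_config()) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(groups)) groups <- as.character(seq_len(n))
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < cv$folds) {
    stop(sprintf("grouped CV needs at least %d groups, have %d",
                 cv$folds, length(tab)), call. = FALSE)
  }
  sizes <- as.numeric(tab); names(sizes) <- names(tab)
  fold_of <- assign_folds(sizes, cv$folds, cv$seed)
  fold <- fold_of[groups]

  # cap the scan at what every training fold can support
  min_train <- min(vapply(seq_len(cv$folds), function(f) sum(fold != f), numeric(1)))
  max_lv <- min(cv$max_lv, ncol(X), min_train - 1)
  if (max_lv < 1) stop("too few samples for cross-validation", call. = FALSE)

  preds <- matrix(NA_real_, n, max_lv)
  for (f in seq_len(cv$folds)) {
    tr <- fold != f
    if (length(unique(groups[tr])) < 2) {
      stop(sprintf("fold %d would train on fewer than 2 groups", f), call. = FALSE)
    }
    x_mean <- colMeans(X[tr, , drop = FALSE])
    y_mean <- mean(y[tr])
    fit <- nipals_pls1(sweep(X[tr, , drop = FALSE], 2, x_mean), y[tr] - y_mean,
                       max_lv)
    Xv <- sweep(X[!tr, , drop = FALSE], 2, x_mean)
    a_eff <- max(fit$n_extracted, 1)
    for (a in seq_len(max_lv)) {
      B <- pls_coefficients(fit, min(a, a_eff))
      preds[!tr, a] <- drop(Xv %*% B) + y_mean
    }
  }
  curve <- vapply(seq_len(max_lv), function(a) {
    sqrt(mean((preds[, a] - y)^2))
  }, numeric(1))
  names(curve) <- paste0("lv", seq_len(max_lv))
  attr(curve, "n_lv_effective") <- max_lv
  curve
}

#' Parsimonious latent-variable selection
#'
#' Returns the smallest LV count whose RMSECV lies within `tolerance`
#' (relative, default 1%) of the curve minimum; exact ties go to the smaller
#' count. The raw argmin of a noisy RMSECV curve tends to overfit; this rule
#' trades a bounded RMSECV concession for fewer components.
#'
#' @param curve RMSECV values at LV counts `1..length(curve)`.
#' @param tolerance Relative tolerance (default 0.01).
#' @return Integer: the chosen LV count.
#' @export
select_latent_variables <- function(curve, tolerance = 0.01) {
  if (length(curve) == 0) stop("empty RMSECV curve", call. = FALSE)
  as.integer(which(curve <= min(curve) * (1 + tolerance))[1])
}

#' Split a spectra set into training and test sets by batch
#'
#' Whole batches are assigned to one side (spectra within a batch are
#' serially correlated; a per-spectrum split would overstate test
#' performance). A seeded random batch order is scanned for the prefix whose
#' spectrum count comes closest to the target fraction, keeping both sides
#' non-empty.
#'
#' @param set A [spectra_set()] with at least 2 batches.
#' @param fraction Target training fraction of spectra, in (0, 1); default 0.7.
#' @param seed Integer seed.
#' @return List with `train` and `test` [spectra_set()]s.
#' @export
split_train_test <- function(set, fraction = 0.7, seed = 1) {
  if (fraction <= 0 || fraction >= 1) {
    stop("fraction must be inside (0, 1)", call. = FALSE)
  }
  batches <- unique(set$reference$batch_id)
  if (length(batches) < 2) stop("need at least 2 batches to split", call. = FALSE)
  set.seed(seed)
  ord <- sample(batches)
  counts <- vapply(ord, function(b) sum(set$reference$batch_id == b), numeric(1))
  cum <- cumsum(counts)
  target <- fraction * sum(counts)
  k <- which.min(abs(cum[-length(cum)] - target))  # keep test side non-empty
  train_batches <- ord[seq_len(k)]
  take <- set$reference$batch_id %in% train_batches
  subset_rows <- function(rows) {
    spectra_set(set$grid, set$intensities[rows, , drop = FALSE],
                set$reference[rows, , drop = FALSE], fingerprint = set$fingerprint)
  }
  list(train = subset_rows(take), test = subset_rows(!take))
}

#' Calibrate one analyte model on a preprocessed set
#'
#' Runs grouped cross-validation over LV counts, applies the parsimonious
#' selection rule and refits on all samples with the chosen count. Samples
#' with a missing reference value for the analyte are excluded.
#'
#' @param set A preprocessed [spectra_set()].
#' @param analyte Analyte name; `paste0(analyte, "_g_L")` must exist in the
#'   reference table.
#' @param cv A [cv_config()]; folds are reduced to the available batch count
#'   when necessary.
#' @return A [fit_pls()] model carrying the RMSECV curve, chosen LV,
#'   fingerprint and grid.
#' @export
fit_analyte_model <- function(set, analyte, cv = cv_config()) {
  col <- paste0(analyte, "_g_L")
  if (!col %in% names(set$reference)) {
    stop(sprintf("reference table has no column '%s'", col), call. = FALSE)
  }
  keep <- !is.na(set$reference[[col]])
  X <- set$intensities[keep, , drop = FALSE]
  y <- set$reference[[col]][keep]
  groups <- if (!is.null(cv$group_by)) set$reference[[cv$group_by]][keep]
  n_groups <- length(unique(groups %||% seq_along(y)))
  if (n_groups < cv$folds) {
    cv$folds <- as.integer(max(2, n_groups))
  }
  curve <- cross_validate(X, y, groups, cv)
  chosen <- select_latent_variables(curve, cv$tolerance)
  fit_pls(X, y, chosen, analyte = analyte, fingerprint = set$fingerprint,
          grid = set$grid, rmsecv = curve)
}

#' Serialize a PLS model to JSON
#'
#' Full-precision JSON so a round-trip through [read_pls_model()] reproduces
#' predictions bit-identically.
#'
#' @param model A [fit_pls()] model.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_pls_model <- function(model, path) {
  payload <- list(
    format = "ramanpls/pls_model", version = "1",
    analyte = model$analyte, n_lv = model$n_lv,
    x_mean = model$x_mean, y_mean = model$y_mean,
    W = model$W, P = model$P, q = model$q,
    coefficients = model$coefficients,
    rmsecv = as.numeric(model$rmsecv),
    fingerprint = model$fingerprint, grid = model$grid)
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       matrix = "columnmajor")
  invisible(path)
}

#' Load a PLS model from JSON
#'
#' @param path Path written by [write_pls_model()].
#' @return A `pls_model`.
#' @export
read_pls_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "ramanpls/pls_model")) {
    stop("not a serialized PLS model", call. = FALSE)
  }
  rmsecv <- as.numeric(unlist(p$rmsecv))
  if (length(rmsecv) == 0) rmsecv <- NULL
  structure(list(analyte = p$analyte, x_mean = p$x_mean, y_mean = p$y_mean,
                 W = as.matrix(p$W), P = as.matrix(p$P), q = p$q,
                 coefficients = p$coefficients, n_lv = as.integer(p$n_lv),
                 rmsecv = rmsecv,
                 fingerprint = p$fingerprint %||% NA_character_,
                 grid = p$grid),
            class = "pls_model")
}
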
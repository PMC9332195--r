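#' Run the generic-calibration transfer experiment end to end
#'
#' Reproduces the structure of the multi-site study on seeded synthetic data:
#'
#' 1. generate the multi-site calibration corpus, an external dilution series
#'    on a fifth (held-out) instrument, and an independent culture run on a
#'    sixth instrument;
#' 2. standardize everything onto the common grid and preprocess (SG first
#'    derivative + SNV);
#' 3. fit pooled ("generic") PLS models per analyte with batch-grouped
#'    cross-validated LV selection, plus per-site glucose models;
#' 4. score every model on its calibration split (SEC%), held-out test split
#'    (SEP%), the external dilution series, and - for the pooled glucose and
#'    lactate models - the independent culture.
#'
#' The central comparison is external validation: single-site models carry
#' their own instrument's quirks into the coefficients and degrade on the
#' held-out instrument, while the pooled model has the instrument-to-
#' instrument variance inside its calibration.
#'
#' @param config Optional list overriding defaults: `site_specs`,
#'   `dilution` (args for [generate_dilution_series()]), `analytes`,
#'   `preprocess` ([preprocess_config()]), `cv` ([cv_config()]),
#'   `split_fraction`, `independent_n`.
#' @param seed Integer master seed; every stage derives its own stream from it.
#' @return List with `report` (data frame of [evaluation_report()] rows, plus
#'   an `lv` column), `models` (pooled models by analyte), `site_models`
#'   (per-site glucose models), and `predictions` for the external and
#'   independent sets.
#' @export
run_generic_experiment <- function(config = list(), seed = 20220726) {
  site_specs <- config$site_specs %||% site_specs_desk()
  analytes <- config$analytes %||% c("glucose", "lactate", "glutamine", "glutamate")
  pp <- config$preprocess %||% preprocess_config()
  cv <- config$cv %||% cv_config(seed = derive_seed(seed, 4))
  frac <- config$split_fraction %||% 0.7

  message("generating synthetic datasets ...")
  sites_raw <- generate_multisite_dataset(site_specs, seed = derive_seed(seed, 1))
  dil_args <- config$dilution %||% list()
  dil_args$seed <- derive_seed(seed, 2)
  dilution_raw <- do.call(generate_dilution_series, dil_args)
  indep_raw <- generate_independent_culture(
    n_spectra = config$independent_n %||% 15, seed = derive_seed(seed, 3))

  message("standardizing and preprocessing ...")
  grid <- default_target_grid()
  sites <- lapply(sites_raw, function(s) preprocess_set(standardize_set(s, grid), pp))
  dilution <- preprocess_set(standardize_set(dilution_raw, grid), pp)
  indep <- preprocess_set(standardize_set(indep_raw, grid), pp)
  pooled <- pool_sets(sites)

  score <- function(model, set, analyte, role, condition) {
    col <- paste0(analyte, "_g_L")
    keep <- !is.na(set$reference[[col]])
    sub <- spectra_set(set$grid, set$intensities[keep, , drop = FALSE],
                       set$reference[keep, , drop = FALSE], set$fingerprint)
    pred <- predict(model, sub)
    row <- evaluation_report(analyte, pred, sub$reference[[col]], role, condition)
    row$lv <- model$n_lv
    list(row = row, predicted = pred, reference = sub$reference[[col]])
  }

  report <- list()
  models <- list()
  predictions <- list()

  message("calibrating pooled generic models ...")
  split <- split_train_test(pooled, frac, derive_seed(seed, 5))
  for (a in analytes) {
    m <- fit_analyte_model(split$train, a, cv)
    models[[a]] <- m
    report[[length(report) + 1]] <- score(m, split$train, a, "calibration", "pooled")$row
    report[[length(report) + 1]] <- score(m, split$test, a, "test", "pooled")$row
    ext <- score(m, dilution, a, "external", "pooled")
    report[[length(report) + 1]] <- ext$row
    predictions$external[[a]] <- ext[c("predicted", "reference")]
  }
  for (a in intersect(c("glucose", "lactate"), analytes)) {
    ind <- score(models[[a]], indep, a, "independent", "pooled")
    report[[length(report) + 1]] <- ind$row
    predictions$independent[[a]] <- ind[c("predicted", "reference")]
  }

  message("calibrating single-site glucose models ...")
  site_models <- list()
  if ("glucose" %in% analytes) {
    for (s in names(sites)) {
      ssplit <- split_train_test(sites[[s]], frac, derive_seed(seed, 6))
      scv <- cv
      scv$seed <- derive_seed(seed, 7)
      m <- fit_analyte_model(ssplit$train, "glucose", scv)
      site_models[[s]] <- m
      report[[length(report) + 1]] <- score(m, ssplit$train, "glucose", "calibration", s)$row
      report[[length(report) + 1]] <- score(m, ssplit$test, "glucose", "test", s)$row
      report[[length(report) + 1]] <- score(m, dilution, "glucose", "external", s)$row
    }
  }

  report <- do.call(rbind, report)
  rownames(report) <- NULL
  check_report_consistency(report)
  list(report = report, models = models, site_models = site_models,
       predictions = predictions)
}
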
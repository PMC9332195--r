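test_that("the transfer experiment report has the expected structure", {
  res <- suppressMessages(run_generic_experiment(seed = 20220726))
  rep <- res$report
  # pooled: 4 analytes x (calibration/test/external) + 2 independent rows;
  # single-site glucose: 4 sites x (calibration/test/external)
  expect_identical(nrow(rep), 4L * 3L + 2L + 4L * 3L)
  expect_true(all(is.finite(rep$sep_percent)))
  expect_true(check_report_consistency(rep))
  # SEC and SEP rows use the identical formula; the role tag is metadata only
  cal <- rep[rep$role == "calibration", ]
  expect_equal(cal$sep_percent, 100 * cal$rmse_g_L / cal$yrange_g_L)

  # every pooled model is far more parsimonious than the scanned maximum
  lv <- vapply(res$models, `[[`, integer(1), "n_lv")
  expect_true(all(lv < 10))

  # the weak-signal analyte is the worst analyte on external validation
  ext <- rep[rep$role == "external" & rep$condition == "pooled", ]
  expect_identical(ext$analyte[which.max(ext$sep_percent)], "glutamate")

  # the independent culture's narrow glucose range inflates its range-relative
  # error relative to lactate, despite similar absolute errors
  ind <- rep[rep$role == "independent", ]
  expect_identical(nrow(ind), 2L)
  expect_true(all(ind$yrange_g_L < 5))
})

test_that("experiment reruns with one seed are identical, different seeds differ", {
  cfg <- list(analytes = "glucose",
              site_specs = site_specs_desk()[c(1, 3)],
              independent_n = 5)
  a <- suppressMessages(run_generic_experiment(cfg, seed = 31))
  b <- suppressMessages(run_generic_experiment(cfg, seed = 31))
  c <- suppressMessages(run_generic_experiment(cfg, seed = 32))
  expect_identical(a$report, b$report)
  expect_false(identical(a$report$rmse_g_L, c$report$rmse_g_L))
})
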
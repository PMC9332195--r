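test_that("rmse follows the root-mean-square formula", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(2, 4), c(1, 2)), sqrt(5 / 2))
  expect_equal(rmse(c(2, 4), c(1, 2)), rmse(c(1, 2), c(2, 4)))
  expect_error(rmse(numeric(0), numeric(0)), "non-empty")
})

test_that("range-relative errors behave like Eq.-2 percentages", {
  ref <- generate_dilution_series(seed = 1)$reference$glucose_g_L
  expect_equal(max(ref) - min(ref), 97)
  expect_equal(sep_percent(4.85, ref), 5.0)
  expect_equal(sep_percent(0, ref), 0)
  # scale invariance: doubling reference and RMSE leaves SEP% unchanged
  expect_equal(sep_percent(4.85, ref), sep_percent(9.7, 2 * ref))
  expect_error(sep_percent(1, rep(3, 5)), "range")
})

test_that("coefficient of determination matches its definition", {
  y <- c(1, 2, 3, 4)
  expect_equal(r_squared(y, y), 1)
  expect_equal(r_squared(rep(mean(y), 4), y), 0)
  expect_lt(r_squared(rev(y), y), 0)
  expect_equal(r_squared(2 * y + 1, y, method = "pearson"), 1)
  expect_error(r_squared(y, rep(2, 4)), "constant")
})

test_that("0-1 scaling is invertible and leaves SEP% unchanged", {
  v <- c(3, 50, 100)
  sc <- minmax_scale(v)
  expect_equal(sc$scaled, c(0, 47 / 97, 1))
  expect_equal(minmax_invert(sc$scaled, sc), v, tolerance = 1e-12)

  set.seed(3)
  ref <- runif(20, 3, 100)
  pred <- ref + rnorm(20)
  s_ref <- minmax_scale(ref)
  scale_fun <- function(x) (x - s_ref$min) / (s_ref$max - s_ref$min)
  raw <- sep_percent(rmse(pred, ref), ref)
  scaled <- sep_percent(rmse(scale_fun(pred), s_ref$scaled), s_ref$scaled)
  expect_equal(raw, scaled, tolerance = 1e-10)
  expect_error(minmax_scale(rep(1, 3)), "range")
})

test_that("evaluation reports are self-consistent and annotated", {
  set.seed(4)
  ref <- runif(25, 0, 10)
  pred <- ref + rnorm(25, 0, 0.2)
  row <- evaluation_report("glucose", pred, ref, "test", "pooled")
  expect_equal(row$sep_percent, 100 * row$rmse_g_L / row$yrange_g_L)
  expect_true(check_report_consistency(row))
  expect_identical(row$n, 25L)

  good <- evaluation_report("a", ref, ref + 1e-9, "calibration")
  expect_identical(good$quality, "very good")
  bad <- evaluation_report("a", ref * 0 + mean(ref), ref, "external")
  expect_identical(bad$quality, "too high")

  row$sep_percent <- row$sep_percent + 1
  expect_error(check_report_consistency(row), "inconsistent")
})
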
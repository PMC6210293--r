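test_that("the Youden threshold separates separable classes perfectly", {
  yc <- youden_cutpoint(c(0, 1, 2), c(10, 11, 12))
  expect_equal(yc$threshold, 10)
  expect_equal(yc$sensitivity, 100)
  expect_equal(yc$specificity, 100)
})

test_that("overlapping classes match the exhaustive-scan oracle", {
  yc <- youden_cutpoint(c(0, 5, 10), c(5, 10, 20))
  oracle <- youden_scan_oracle(c(0, 5, 10), c(5, 10, 20))
  expect_equal(yc$threshold, oracle$threshold)
  expect_equal(yc$sensitivity + yc$specificity, oracle$j)
})

test_that("identical class samples land at chance level", {
  x <- c(3, 7, 7, 12)
  yc <- youden_cutpoint(x, x)
  expect_equal(yc$sensitivity + yc$specificity, 100)
  expect_equal(roc_auc(x, x), 0.5)
})

test_that("AUC equals the all-pairs oracle and flips under label swap", {
  set.seed(61)
  for (rep in 1:50) {
    sed <- rpois(sample(2:50, 1), sample(c(5, 30, 100), 1))
    light <- rpois(sample(2:50, 1), sample(c(5, 30, 100), 1))
    a <- roc_auc(sed, light)
    expect_equal(a, auc_allpairs_oracle(sed, light))
    expect_equal(roc_auc(light, sed), 1 - a)
    yc <- youden_cutpoint(sed, light)
    oracle <- youden_scan_oracle(sed, light)
    expect_equal(yc$threshold, oracle$threshold)
    expect_equal(yc$sensitivity + yc$specificity, oracle$j)
  }
  expect_equal(roc_auc(c(0, 1, 2), c(10, 11)), 1.0)
})

test_that("the rank AUC agrees with an external ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(62)
  sed <- rpois(80, 40)
  light <- rpois(60, 90)
  ext <- suppressMessages(pROC::auc(
    response = rep(c(0, 1), c(80, 60)), predictor = c(sed, light),
    direction = "<"))
  expect_equal(roc_auc(sed, light), as.numeric(ext))
})

test_that("the reference activity is the highest-count seated task", {
  mk <- function(act, counts) tibble::tibble(
    child_id = "c1", wrist = "non_dominant", activity = act,
    epoch_index = seq_along(counts) - 1L, axis1 = as.integer(counts),
    axis2 = 0L, axis3 = 0L)
  tab <- dplyr::bind_rows(mk("Quiet", rep(5, 9)), mk("Busy", rep(60, 9)),
                          mk("Walking", rep(300, 9)))
  expect_equal(select_reference_activity(tab), "Busy")
  one <- mk("Only", rep(4, 5))
  expect_equal(select_reference_activity(one), "Only")
  # identical profiles: lexicographic tie-break
  tied <- dplyr::bind_rows(mk("Beta", rep(10, 9)), mk("Alpha", rep(10, 9)))
  expect_equal(select_reference_activity(tied), "Alpha")
  # tie on the median broken by the 75th percentile
  q75 <- dplyr::bind_rows(mk("Low", c(0, 10, 10, 10, 12)),
                          mk("High", c(0, 10, 10, 10, 90)))
  expect_equal(select_reference_activity(q75), "High")
  expect_error(select_reference_activity(mk("Walking", 1:5)), "no seated")
})

separable_epochs <- function(n_children = 20, epochs = 12) {
  # every child's light block contains the class minimum (50), so every
  # training subset derives the same threshold
  sed <- rep(c(0L, 3L, 8L), length.out = epochs)
  light <- c(50L, rep(c(55L, 60L), length.out = epochs - 1))
  mk <- function(cid, act, x) tibble::tibble(
    child_id = cid, wrist = "non_dominant", activity = act,
    epoch_index = seq_along(x) - 1L, axis1 = x, axis2 = 0L, axis3 = 0L)
  dplyr::bind_rows(lapply(sprintf("c%02d", seq_len(n_children)), function(cid)
    dplyr::bind_rows(mk(cid, "Seated", sed), mk(cid, "Walking", light))))
}

test_that("separable classes yield perfect folds and a gap threshold", {
  tab <- separable_epochs()
  cfg <- calibration_config(k = 5, seed = 7, signals = "axis1",
                            validation_B = 50)
  r <- calibrate(tab, cfg, wrist = "non_dominant", signal = "axis1")
  expect_true(all(r$folds$sensitivity == 100))
  expect_true(all(r$folds$specificity == 100))
  expect_true(all(r$folds$auc == 1))
  expect_gt(r$cutpoint, 8)
  expect_lte(r$cutpoint, 50)
  expect_equal(r$auc_validation, 1)
})

test_that("fold count does not matter in the separable limit", {
  tab <- separable_epochs(n_children = 30)
  r2 <- calibrate(tab, calibration_config(k = 2, seed = 8, validation_B = 20),
                  "non_dominant", "axis1")
  r10 <- calibrate(tab, calibration_config(k = 10, seed = 8, validation_B = 20),
                   "non_dominant", "axis1")
  expect_equal(r2$cutpoint, r10$cutpoint)
  expect_equal(r2$cutpoint, 50)
})

test_that("folds whose held-out children lack a class are skipped", {
  tab <- separable_epochs(n_children = 4)
  lonely <- tibble::tibble(child_id = "c99", wrist = "non_dominant",
                           activity = "Seated", epoch_index = 0:5,
                           axis1 = rep(c(0L, 5L), 3), axis2 = 0L, axis3 = 0L)
  tab <- dplyr::bind_rows(tab, lonely)
  cfg <- calibration_config(k = 4, calibration_fraction = 0.99, seed = 11,
                            validation_B = 20)
  expect_warning(r <- calibrate(tab, cfg, "non_dominant", "axis1"),
                 "skipped")
  expect_lt(nrow(r$folds), 4)
})

test_that("calibration is deterministic under a fixed seed", {
  tab <- separable_epochs()
  cfg <- calibration_config(k = 5, seed = 12, validation_B = 30)
  r1 <- calibrate(tab, cfg, "non_dominant", "axis1")
  r2 <- calibrate(tab, cfg, "non_dominant", "axis1")
  expect_identical(r1, r2)
})

test_that("the repeats mode also recovers a separating threshold", {
  tab <- separable_epochs()
  cfg <- calibration_config(k = 5, seed = 13, mode = "repeats",
                            validation_B = 20)
  r <- calibrate(tab, cfg, "non_dominant", "axis1")
  expect_equal(r$cutpoint, 50)
  expect_true(all(r$folds$auc == 1))
})
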
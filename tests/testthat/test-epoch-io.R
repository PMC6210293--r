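mk_series <- function(n = 3) {
  tibble::tibble(child_id = "c0001", wrist = "dominant",
                 epoch_index = seq_len(n) - 1L,
                 axis1 = as.integer(c(12, 0, 344)[seq_len(n)]),
                 axis2 = as.integer(c(8, 0, 210)[seq_len(n)]),
                 axis3 = as.integer(c(6, 0, 180)[seq_len(n)]))
}

test_that("epoch files round-trip losslessly in both delimiters", {
  for (d in c("comma", "tab")) {
    f <- withr::local_tempfile(fileext = ".csv")
    write_epochs(mk_series(), f, delim = d)
    back <- read_epochs(f)
    expect_equal(as.data.frame(back), as.data.frame(mk_series()),
                 ignore_attr = TRUE)
    expect_equal(attr(back, "epoch_seconds"), 5)
    expect_equal(attr(back, "start"), "2018-07-02T09:00:00")
  }
})

test_that("an empty body with a valid header reads as an empty table", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_epochs(mk_series(0), f)
  back <- read_epochs(f)
  expect_equal(nrow(back), 0)
  expect_setequal(names(back), c("child_id", "wrist", "epoch_index",
                                 "axis1", "axis2", "axis3"))
})

test_that("parse errors name the offending line", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_epochs(mk_series(), f)
  lines <- readLines(f)

  writeLines(c(lines[1:3], "0,5,-2,1"), f)
  expect_error(read_epochs(f), "line 4: negative")

  writeLines(c(lines[1:4], "5,1,1,1"), f)
  expect_error(read_epochs(f), "line 5: epoch_index not contiguous")

  writeLines(c("# not-a-signature", lines[-1]), f)
  expect_error(read_epochs(f), "line 1")

  writeLines(c(lines[1], "# start=x; epoch_seconds=5; delim=pipe", lines[3:4]), f)
  expect_error(read_epochs(f), "line 2: unknown delim")
})

test_that("a cohort directory round-trips through the dialect files", {
  cfg <- generator_config(n_children = 3, epochs_per_activity = 5, seed = 21)
  ds <- generate_dataset(cfg)
  dir <- withr::local_tempdir()
  write_epoch_dataset(ds$epochs, ds$log, dir)
  back <- read_epoch_dataset(dir)
  orig <- dplyr::arrange(ds$epochs, child_id, wrist, activity, epoch_index)
  got <- dplyr::arrange(back$epochs, child_id, wrist, activity, epoch_index)
  expect_equal(as.data.frame(got), as.data.frame(orig), ignore_attr = TRUE)
  expect_equal(as.data.frame(back$log)[order(back$log$child_id, back$log$activity), ],
               as.data.frame(ds$log)[order(ds$log$child_id, ds$log$activity), ],
               ignore_attr = TRUE)
})

test_that("re-integration sums windows and conserves totals", {
  expect_identical(reintegrate(c(4, 7, 1), 1), c(4, 7, 1))
  expect_equal(reintegrate(c(1, 2, 3, 4, 5), 5), 15)
  expect_warning(out <- reintegrate(c(1, 2, 3, 4, 5, 6, 7), 5), "dropping 2")
  expect_equal(out, 15)
  expect_error(reintegrate(1:10, 0), "factor")
  set.seed(31)
  x <- rpois(60, 20)
  expect_equal(sum(reintegrate(x, 12)), sum(x))
})

test_that("vector magnitude is the Euclidean norm and dominates each axis", {
  expect_equal(vector_magnitude(0, 0, 0), 0)
  expect_equal(vector_magnitude(3, 4, 0), 5)
  expect_equal(vector_magnitude(203, 0, 0), 203)
  set.seed(32)
  a <- matrix(rpois(300, 50), ncol = 3)
  vm <- vector_magnitude(a[, 1], a[, 2], a[, 3])
  expect_true(all(vm >= pmax(a[, 1], a[, 2], a[, 3])))
  expect_error(vector_magnitude(-1, 0, 0), "non-negative")
})

test_that("the observation filter drops flagged seated sessions only", {
  cfg <- generator_config(n_children = 4, epochs_per_activity = 6,
                          p_stand = 0, seed = 41)
  ds <- generate_dataset(cfg)

  out <- apply_observation_filter(ds$epochs, ds$log)
  expect_equal(nrow(out), nrow(ds$epochs))  # all verified: identity

  log2 <- ds$log
  flag <- log2$child_id == "c0002" & log2$activity == "Board Games"
  log2$seated_verified[flag] <- FALSE
  out2 <- apply_observation_filter(ds$epochs, log2)
  expect_false(any(out2$child_id == "c0002" & out2$activity == "Board Games"))
  expect_true(any(out2$child_id == "c0002" & out2$activity == "Cards"))
  expect_equal(nrow(dplyr::filter(out2, activity == "Board Games",
                                  wrist == "dominant")), 3 * 6)

  # idempotent
  expect_equal(apply_observation_filter(out2, log2), out2)

  # all seated flags false: only walking survives
  log3 <- dplyr::mutate(ds$log, seated_verified = activity == "Walking")
  out3 <- apply_observation_filter(ds$epochs, log3)
  expect_setequal(unique(out3$activity), "Walking")

  # missing log entry is a contract violation
  expect_error(apply_observation_filter(ds$epochs, ds$log[-1, ]),
               "no observation-log entry")
})

test_that("incomplete sessions are excluded like unverified ones", {
  cfg <- generator_config(n_children = 3, epochs_per_activity = 4,
                          p_stand = 0, seed = 42)
  ds <- generate_dataset(cfg)
  log2 <- dplyr::mutate(ds$log, completed = !(child_id == "c0001" &
                                                activity == "TV"))
  out <- apply_observation_filter(ds$epochs, log2)
  expect_false(any(out$child_id == "c0001" & out$activity == "TV"))
})
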
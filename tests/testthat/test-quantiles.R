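test_that("sample_quantile follows the interpolation convention", {
  expect_equal(sample_quantile(rep(7, 10), 0.25), 7)
  expect_equal(sample_quantile(c(1, 2, 3, 4), 0.5), 2.5)
  set.seed(51)
  x <- rpois(37, 40)
  expect_equal(sample_quantile(x, 0.5), sample_quantile(sample(x), 0.5))
  for (tau in c(0.1, 0.25, 0.5, 0.75, 0.9)) {
    expect_equal(sample_quantile(x, tau), quantile7_oracle(x, tau))
  }
  expect_error(sample_quantile(numeric(0), 0.5), "non-empty")
})

test_that("quantile_diff equals the independent group-quantile oracle", {
  set.seed(52)
  for (rep in 1:50) {
    nd_n <- sample(3:40, 1)
    dom_n <- sample(3:40, 1)
    lcm <- nd_n * dom_n  # make both divisible by n_children = 1
    dom <- rpois(dom_n, sample(5:200, 1))
    nd <- rpois(nd_n, sample(5:200, 1))
    tab <- dplyr::bind_rows(
      tibble::tibble(child_id = "c1", wrist = "dominant", activity = "A",
                     epoch_index = seq_along(dom) - 1L, axis1 = dom,
                     axis2 = 0L, axis3 = 0L),
      tibble::tibble(child_id = "c1", wrist = "non_dominant", activity = "A",
                     epoch_index = seq_along(nd) - 1L, axis1 = nd,
                     axis2 = 0L, axis3 = 0L))
    tau <- sample(c(0.25, 0.5, 0.75), 1)
    expect_equal(quantile_diff(tab, "A", tau),
                 quantile7_oracle(dom, tau) - quantile7_oracle(nd, tau))
  }
})

test_that("quantile_diff matches a quantile-regression fit where the
           check-loss solution is unique", {
  skip_if_not_installed("quantreg")
  set.seed(53)
  for (rep in 1:10) {
    dom <- rpois(41, 120)  # odd sizes: the median is an order statistic
    nd <- rpois(35, 80)
    dat <- data.frame(y = c(dom, nd),
                      dom = rep(c(1, 0), c(length(dom), length(nd))))
    fit <- quantreg::rq(y ~ dom, tau = 0.5, data = dat)
    expect_equal(quantile_diff(toy_epochs(dom, nd, n_children = 1), "Task", 0.5),
                 unname(coef(fit)["dom"]))
  }
})

test_that("identical wrist samples give a zero, non-significant contrast", {
  x <- rep(c(0, 10, 20, 35), 10)
  tab <- toy_epochs(x, x, n_children = 4)
  expect_equal(quantile_diff(tab, "Task", 0.5), 0)
  res <- clustered_bootstrap(tab, "Task", 0.5, bootstrap_config(B = 50, seed = 1))
  expect_equal(res$diff, 0)
  expect_false(res$significant)
})

test_that("an all-zero activity is flagged non-converged like the
           unestimable contrasts", {
  tab <- toy_epochs(rep(0, 40), rep(0, 40), n_children = 4)
  res <- clustered_bootstrap(tab, "Task", 0.5, bootstrap_config(B = 50, seed = 2))
  expect_false(res$converged)
  expect_false(res$significant)
  expect_true(is.na(res$ci_low))
})

test_that("the percentile interval contains the point estimate", {
  set.seed(54)
  dom <- rpois(200, 120)
  nd <- rpois(200, 90)
  tab <- toy_epochs(dom, nd, n_children = 10)
  res <- clustered_bootstrap(tab, "Task", 0.5,
                             cfg = bootstrap_config(B = 1000, seed = 3))
  expect_true(res$converged)
  expect_lte(res$ci_low, res$diff)
  expect_gte(res$ci_high, res$diff)
  expect_true(res$significant)  # true median gap is large
})

test_that("bootstrap resampling is by child, not by epoch", {
  # one extreme child dominates; epoch-level resampling would almost never
  # produce replicates that exclude it entirely, child-level often does
  dom <- c(rep(1000L, 10), rep(10L, 30))
  nd <- rep(10L, 40)
  tab <- toy_epochs(dom, nd, n_children = 4)
  res <- clustered_bootstrap(tab, "Task", 0.75,
                             cfg = bootstrap_config(B = 200, seed = 4))
  # replicates omitting child 1 have diff 0 at the 75th percentile, so the
  # lower CI limit collapses to about 0 despite a large point estimate
  expect_gt(res$diff, 200)
  expect_lt(res$ci_low, 10)
})

test_that("the contrast table mirrors the per-activity layout", {
  set.seed(55)
  busy <- toy_epochs(rpois(40, 120), rpois(40, 80), activity = "Busy",
                     n_children = 4)
  still <- toy_epochs(rep(0L, 40), rep(0L, 40), activity = "Still",
                      n_children = 4)
  tab <- quantile_diff_table(dplyr::bind_rows(busy, still),
                             bootstrap_config(B = 20, seed = 5))
  expect_equal(nrow(tab), 2 * 3)
  expect_setequal(unique(tab$activity), c("Busy", "Still"))
  # a motionless task mirrors the unestimable published rows at every level
  expect_true(all(!tab$converged[tab$activity == "Still"]))
  expect_true(all(is.na(tab$ci_low[tab$activity == "Still"])))
  expect_true(all(tab$converged[tab$activity == "Busy"]))
  expect_true(all(tab$n_children == 4))
  expect_equal(tab$nd_q50[tab$activity == "Still"][1], 0)
})

test_that("contrast validation errors are informative", {
  tab <- toy_epochs(1:10, 1:10, n_children = 1)
  expect_error(quantile_diff(tab, "Missing", 0.5), "absent")
  expect_error(clustered_bootstrap(tab, "Task", 0.5), ">= 2 children")
})
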
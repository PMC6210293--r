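#' Select the reference seated activity
#'
#' The cut-point is derived against the seated sedentary activity producing
#' the highest counts, on the reasoning that a threshold separating the
#' most active seated task from walking classifies every quieter seated
#' task as sedentary a fortiori. Selection is by highest median of the
#' chosen signal on the chosen wrist; ties break by higher 75th percentile,
#' then lexicographically.
#'
#' @param epochs labeled epoch table.
#' @param signal one of `axis1`, `axis2`, `axis3`, `vm`.
#' @param wrist `"dominant"` or `"non_dominant"`.
#' @param light_activities labels treated as light intensity (not seated).
#' @return The reference activity label.
#' @export
select_reference_activity <- function(epochs, signal = "axis1",
                                      wrist = "non_dominant",
                                      light_activities = "Walking") {
  assert_wrist(wrist)
  assert_epoch_table(epochs, need = c("wrist", "activity", signal))
  seated <- dplyr::filter(epochs, !.data$activity %in% light_activities,
                          .data$wrist == !!wrist)
  if (nrow(seated) == 0L) abort_wc("no seated epochs to choose a reference from")
  stats_tab <- dplyr::summarise(
    dplyr::group_by(seated, .data$activity),
    med = median(.data[[signal]]),
    q75 = sample_quantile(.data[[signal]], 0.75),
    .groups = "drop")
  stats_tab <- stats_tab[order(-stats_tab$med, -stats_tab$q75,
                               stats_tab$activity), ]
  stats_tab$activity[1]
}

#' Youden-optimal count threshold
#'
#' Scans every distinct observed count (plus one beyond the maximum) as a
#' candidate threshold under the rule `count >= threshold` is light,
#' `count < threshold` is sedentary, and returns the candidate maximizing
#' sensitivity + specificity (the Youden criterion). Sensitivity is the
#' percentage of light epochs at or above the threshold; specificity the
#' percentage of sedentary epochs below it. Ties go to the smallest
#' threshold.
#'
#' @param sedentary_counts,light_counts non-empty count vectors for the two
#'   classes.
#' @return A list with `threshold` (counts/5 s), `sensitivity` and
#'   `specificity` (percent).
#' @export
youden_cutpoint <- function(sedentary_counts, light_counts) {
  if (length(sedentary_counts) == 0L || length(light_counts) == 0L) {
    abort_wc("both classes must be non-empty")
  }
  cand <- sort(unique(c(sedentary_counts, light_counts)))
  cand <- c(cand, max(cand) + 1)
  # vectorised: counts >= t via empirical CDFs at t - 0 (left limit)
  sens <- vapply(cand, function(t) mean(light_counts >= t) * 100, numeric(1))
  spec <- vapply(cand, function(t) mean(sedentary_counts < t) * 100, numeric(1))
  j <- sens + spec
  # fuzzy maximum so float noise cannot override the smallest-threshold
  # tie-break (J values are sums of rational percentages)
  best <- which(j >= max(j) - 1e-9)[1]
  list(threshold = cand[best], sensitivity = sens[best],
       specificity = spec[best])
}

#' Area under the ROC curve by rank statistic
#'
#' The probability that a randomly drawn light epoch registers more counts
#' than a randomly drawn sedentary epoch, counting ties as one half — the
#' Mann-Whitney form, identical to the trapezoidal area under the
#' empirical ROC curve.
#'
#' @inheritParams youden_cutpoint
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(sedentary_counts, light_counts) {
  ns <- length(sedentary_counts)
  nl <- length(light_counts)
  if (ns == 0L || nl == 0L) abort_wc("both classes must be non-empty")
  r <- rank(c(light_counts, sedentary_counts), ties.method = "average")
  (sum(r[seq_len(nl)]) - nl * (nl + 1) / 2) / (nl * ns)
}

#' Calibration configuration
#'
#' @param k number of folds (>= 2; the calibration analysis used 10).
#' @param calibration_fraction share of children assigned to the
#'   calibration set, the remainder forming the held-out validation set
#'   (default 100/167, the published split).
#' @param seed integer seed for the split and fold assignment.
#' @param signals subset of `axis1`, `axis2`, `axis3`, `vm`.
#' @param mode `"cv"`: derive the threshold on k-1 folds and evaluate on
#'   the held-out fold, repeated over folds; `"repeats"`: k independent
#'   child-level bootstrap resamples of the calibration set, each
#'   evaluated in-sample (the alternative reading of a "10-fold ROC").
#' @param eval `"out_of_fold"` or `"in_fold"` metric evaluation under
#'   `mode = "cv"`.
#' @param pooled_sedentary if TRUE, all seated activities enter the ROC
#'   rather than only the highest-count reference activity.
#' @param validation_B bootstrap replicates (over children) for the
#'   validation AUC confidence interval.
#' @return A list of class `calibration_config`.
#' @export
calibration_config <- function(k = 10L, calibration_fraction = 100 / 167,
                               seed = 20180926L,
                               signals = c("axis1", "axis2", "axis3", "vm"),
                               mode = c("cv", "repeats"),
                               eval = c("out_of_fold", "in_fold"),
                               pooled_sedentary = FALSE,
                               validation_B = 200L) {
  k <- assert_count(k, "k", lower = 2L)
  assert_scalar_number(calibration_fraction, "calibration_fraction",
                       lower = 1e-9, upper = 1 - 1e-9)
  seed <- assert_count(seed, "seed", lower = 0L)
  signals <- match.arg(signals, c("axis1", "axis2", "axis3", "vm"),
                       several.ok = TRUE)
  structure(list(k = k, calibration_fraction = calibration_fraction,
                 seed = seed, signals = signals, mode = match.arg(mode),
                 eval = match.arg(eval),
                 pooled_sedentary = isTRUE(pooled_sedentary),
                 validation_B = assert_count(validation_B, "validation_B",
                                             lower = 2L)),
            class = "calibration_config")
}

.class_counts <- function(epochs, wrist, signal, light_activities,
                          reference_activity, pooled) {
  sub <- dplyr::filter(epochs, .data$wrist == !!wrist)
  light <- dplyr::filter(sub, .data$activity %in% light_activities)
  sed <- if (pooled) {
    dplyr::filter(sub, !.data$activity %in% light_activities)
  } else {
    dplyr::filter(sub, .data$activity == reference_activity)
  }
  list(sed = sed, light = light)
}

.metrics_at <- function(threshold, sed, light) {
  list(sensitivity = mean(light >= threshold) * 100,
       specificity = mean(sed < threshold) * 100)
}

#' Derive a cut-point by k-fold ROC calibration with held-out validation
#'
#' Children are split once (seeded) into a calibration and a validation
#' set. Calibration children are partitioned into `k` folds at the child
#' level; for each fold the Youden threshold is derived on the remaining
#' folds and its sensitivity, specificity and AUC are evaluated on the
#' held-out fold. Thresholds and metrics are averaged over folds; the
#' averaged threshold is then evaluated on the validation children, whose
#' AUC receives a child-level bootstrap confidence interval. Only walking
#' and the highest-count seated activity enter the ROC unless
#' `pooled_sedentary` is set in the config.
#'
#' @param epochs labeled (and observation-filtered) epoch table; must
#'   contain a `vm` column if `signal = "vm"` (see [add_vm()]).
#' @param cfg a [calibration_config()].
#' @param wrist wrist to calibrate.
#' @param signal signal to calibrate on.
#' @param light_activities labels of the light-intensity class.
#' @return A list of class `cutpoint_result`: `signal`, `wrist`,
#'   `reference_activity`, `cutpoint` (mean over folds), `cutpoint_rounded`,
#'   `sensitivity`, `specificity` (fold means, percent), `auc_calibration`
#'   with `auc_calibration_ci`, `auc_validation` with `auc_validation_ci`,
#'   `sensitivity_validation`, `specificity_validation`, `n_calibration`,
#'   `n_validation`, and a `folds` tibble of per-fold results.
#' @export
calibrate <- function(epochs, cfg = calibration_config(),
                      wrist = "non_dominant", signal = "axis1",
                      light_activities = "Walking") {
  stopifnot(inherits(cfg, "calibration_config"))
  assert_wrist(wrist)
  assert_epoch_table(epochs, need = c("child_id", "wrist", "activity", signal))

  ref <- select_reference_activity(epochs, signal, wrist, light_activities)
  cls <- .class_counts(epochs, wrist, signal, light_activities, ref,
                       cfg$pooled_sedentary)
  if (nrow(cls$sed) == 0L || nrow(cls$light) == 0L) {
    abort_wc("need epochs in both the sedentary and light class")
  }

  children <- sort(unique(c(cls$sed$child_id, cls$light$child_id)))
  n_cal <- max(2L, round(cfg$calibration_fraction * length(children)))
  if (n_cal >= length(children)) n_cal <- length(children) - 1L

  withr::with_seed(cfg$seed, {
    cal_children <- sort(sample(children, n_cal))
    val_children <- setdiff(children, cal_children)
    fold_of <- sample(rep(seq_len(cfg$k), length.out = n_cal))
    boot_draws <- replicate(cfg$k,
                            sample(cal_children, n_cal, replace = TRUE),
                            simplify = FALSE)
    val_boot <- replicate(cfg$validation_B,
                          sample(val_children, length(val_children),
                                 replace = TRUE), simplify = FALSE)
  })

  pick <- function(tab, ids) {
    counts <- tab[[signal]]
    blocks <- split(counts, factor(tab$child_id, levels = children))
    unlist(blocks[ids], use.names = FALSE)
  }

  folds <- list()
  for (i in seq_len(cfg$k)) {
    if (cfg$mode == "cv") {
      train_ids <- cal_children[fold_of != i]
      test_ids <- cal_children[fold_of == i]
      train_sed <- pick(cls$sed, train_ids)
      train_light <- pick(cls$light, train_ids)
      if (length(train_sed) == 0L || length(train_light) == 0L) {
        warning(sprintf("fold %d skipped: training data missing a class", i),
                call. = FALSE)
        next
      }
      yc <- youden_cutpoint(train_sed, train_light)
      if (cfg$eval == "out_of_fold") {
        eval_sed <- pick(cls$sed, test_ids)
        eval_light <- pick(cls$light, test_ids)
      } else {
        eval_sed <- train_sed
        eval_light <- train_light
      }
    } else {  # repeats: bootstrap resample, in-sample evaluation
      ids <- boot_draws[[i]]
      eval_sed <- pick(cls$sed, ids)
      eval_light <- pick(cls$light, ids)
      if (length(eval_sed) == 0L || length(eval_light) == 0L) {
        warning(sprintf("repeat %d skipped: resample missing a class", i),
                call. = FALSE)
        next
      }
      yc <- youden_cutpoint(eval_sed, eval_light)
    }
    if (length(eval_sed) == 0L || length(eval_light) == 0L) {
      warning(sprintf("fold %d skipped: held-out data missing a class", i),
              call. = FALSE)
      next
    }
    m <- .metrics_at(yc$threshold, eval_sed, eval_light)
    folds[[length(folds) + 1L]] <- tibble::tibble(
      fold_id = i, cutpoint = yc$threshold,
      sensitivity = m$sensitivity, specificity = m$specificity,
      auc = roc_auc(eval_sed, eval_light))
  }
  if (length(folds) == 0L) abort_wc("all folds skipped; cannot calibrate")
  folds <- dplyr::bind_rows(folds)

  k_eff <- nrow(folds)
  cut_mean <- mean(folds$cutpoint)
  auc_mean <- mean(folds$auc)
  auc_half <- 1.96 * sd(folds$auc) / sqrt(k_eff)

  val_sed <- pick(cls$sed, val_children)
  val_light <- pick(cls$light, val_children)
  if (length(val_sed) && length(val_light)) {
    auc_val <- roc_auc(val_sed, val_light)
    val_m <- .metrics_at(cut_mean, val_sed, val_light)
    boot_auc <- vapply(val_boot, function(ids) {
      s <- pick(cls$sed, ids); l <- pick(cls$light, ids)
      if (length(s) == 0L || length(l) == 0L) return(NA_real_)
      roc_auc(s, l)
    }, numeric(1))
    boot_auc <- boot_auc[is.finite(boot_auc)]
    auc_val_ci <- unname(quantile(boot_auc, c(0.025, 0.975), type = 7))
  } else {
    auc_val <- NA_real_
    val_m <- list(sensitivity = NA_real_, specificity = NA_real_)
    auc_val_ci <- c(NA_real_, NA_real_)
  }

  structure(list(
    signal = signal, wrist = wrist, reference_activity = ref,
    cutpoint = cut_mean, cutpoint_rounded = as.integer(round(cut_mean)),
    sensitivity = mean(folds$sensitivity),
    specificity = mean(folds$specificity),
    auc_calibration = auc_mean,
    auc_calibration_ci = c(auc_mean - auc_half, auc_mean + auc_half),
    auc_validation = auc_val, auc_validation_ci = auc_val_ci,
    sensitivity_validation = val_m$sensitivity,
    specificity_validation = val_m$specificity,
    n_calibration = n_cal, n_validation = length(val_children),
    folds = folds), class = "cutpoint_result")
}

#' @export
print.cutpoint_result <- function(x, ...) {
  cat(sprintf(
    paste0("<cutpoint_result> %s, %s wrist (reference: %s)\n",
           "  cut-point %.1f counts/5 s (rounded %d)\n",
           "  sensitivity %.1f%%  specificity %.1f%%\n",
           "  AUC calibration %.3f (%.3f-%.3f), validation %.3f (%.3f-%.3f)\n",
           "  children: %d calibration / %d validation\n"),
    x$signal, x$wrist, x$reference_activity, x$cutpoint, x$cutpoint_rounded,
    x$sensitivity, x$specificity, x$auc_calibration,
    x$auc_calibration_ci[1], x$auc_calibration_ci[2], x$auc_validation,
    x$auc_validation_ci[1], x$auc_validation_ci[2],
    x$n_calibration, x$n_validation))
  invisible(x)
}

#' Calibrate every requested signal on both wrists
#'
#' @inheritParams calibrate
#' @return A list with `results` (tibble, one row per wrist by signal) and
#'   `folds` (tibble of per-fold metrics).
#' @export
calibrate_all <- function(epochs, cfg = calibration_config(),
                          light_activities = "Walking") {
  if ("vm" %in% cfg$signals && !"vm" %in% names(epochs)) {
    epochs <- add_vm(epochs)
  }
  rows <- list(); folds <- list()
  for (w in WRISTS) {
    for (s in cfg$signals) {
      r <- calibrate(epochs, cfg, wrist = w, signal = s,
                     light_activities = light_activities)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        wrist = w, signal = s, reference_activity = r$reference_activity,
        cutpoint = r$cutpoint, cutpoint_rounded = r$cutpoint_rounded,
        sensitivity = r$sensitivity, specificity = r$specificity,
        auc_calibration = r$auc_calibration,
        auc_calibration_lo = r$auc_calibration_ci[1],
        auc_calibration_hi = r$auc_calibration_ci[2],
        auc_validation = r$auc_validation,
        auc_validation_lo = r$auc_validation_ci[1],
        auc_validation_hi = r$auc_validation_ci[2],
        sensitivity_validation = r$sensitivity_validation,
        specificity_validation = r$specificity_validation,
        n_calibration = r$n_calibration, n_validation = r$n_validation)
      folds[[length(folds) + 1L]] <- dplyr::mutate(r$folds, wrist = w,
                                                   signal = s, .before = 1)
    }
  }
  list(results = dplyr::bind_rows(rows), folds = dplyr::bind_rows(folds))
}
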
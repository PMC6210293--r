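#' Linear-interpolation sample quantile
#'
#' The package-wide quantile convention: linear interpolation between order
#' statistics at position `(n - 1) * tau` (the common "type 7" scheme).
#'
#' @param values non-empty numeric vector.
#' @param tau quantile level in `[0, 1]`.
#' @return The sample quantile as a single number.
#' @export
sample_quantile <- function(values, tau) {
  if (length(values) == 0L || any(!is.finite(values))) {
    abort_wc("`values` must be non-empty and finite")
  }
  assert_scalar_number(tau, "tau", lower = 0, upper = 1)
  unname(quantile(values, probs = tau, type = 7, names = FALSE))
}

#' Dominant-minus-non-dominant quantile difference for one activity
#'
#' The tau-quantile-regression coefficient of the wrist indicator in the
#' saturated one-binary-covariate design, which equals the difference of
#' the two groups' sample quantiles under the package's fixed
#' interpolation convention. Positive values mean the dominant wrist
#' registers higher counts.
#'
#' @param epochs labeled epoch table containing both wrists.
#' @param activity activity label to compare.
#' @param tau quantile level (0.25, 0.5 or 0.75 in the calibration
#'   analysis; any level in `(0, 1)` is accepted).
#' @param signal which per-epoch signal to compare (default axis 1, the
#'   axis the calibration analysis uses).
#' @return Difference in counts/5 s (dominant minus non-dominant).
#' @export
quantile_diff <- function(epochs, activity, tau, signal = "axis1") {
  assert_epoch_table(epochs, need = c("child_id", "wrist", "activity", signal))
  sub <- dplyr::filter(epochs, .data$activity == !!activity)
  if (nrow(sub) == 0L) abort_wc("activity '%s' absent from epoch table", activity)
  dom <- sub[[signal]][sub$wrist == "dominant"]
  nd <- sub[[signal]][sub$wrist == "non_dominant"]
  if (length(dom) == 0L || length(nd) == 0L) {
    abort_wc("activity '%s' lacks one wrist", activity)
  }
  sample_quantile(dom, tau) - sample_quantile(nd, tau)
}

#' Bootstrap configuration for clustered quantile contrasts
#'
#' @param B number of bootstrap replicates (>= 2; the calibration analysis
#'   used 100).
#' @param alpha two-sided confidence level complement (0.05 gives 95% CIs).
#' @param seed integer seed.
#' @return A list of class `bootstrap_config`.
#' @export
bootstrap_config <- function(B = 100L, alpha = 0.05, seed = 20180926L) {
  B <- assert_count(B, "B", lower = 2L)
  assert_scalar_number(alpha, "alpha", lower = 1e-12, upper = 1 - 1e-12)
  seed <- assert_count(seed, "seed", lower = 0L)
  structure(list(B = B, alpha = alpha, seed = seed),
            class = "bootstrap_config")
}

#' Child-clustered bootstrap CI for a quantile difference
#'
#' Resamples whole children with replacement (children appearing k times
#' contribute k copies of their full epoch blocks on both wrists),
#' recomputes the dominant-minus-non-dominant quantile difference on each
#' replicate, and forms a percentile interval. The contrast is flagged
#' non-converged when the replicate distribution is degenerate (zero
#' spread) or when both wrists' point quantiles sit in the atom at zero —
#' the situations in which the published contrasts could not be estimated.
#'
#' @inheritParams quantile_diff
#' @param cfg a [bootstrap_config()].
#' @return A one-row tibble: `activity`, `tau`, `diff`, `ci_low`,
#'   `ci_high`, `converged`, `significant` (`significant` is TRUE iff
#'   converged and the CI excludes 0).
#' @export
clustered_bootstrap <- function(epochs, activity, tau, cfg = bootstrap_config(),
                                signal = "axis1") {
  stopifnot(inherits(cfg, "bootstrap_config"))
  sub <- dplyr::filter(epochs, .data$activity == !!activity)
  if (nrow(sub) == 0L) abort_wc("activity '%s' absent from epoch table", activity)
  children <- unique(sub$child_id)
  if (length(children) < 2L) {
    abort_wc("clustered bootstrap needs >= 2 children, got %d", length(children))
  }
  dom_blocks <- split(sub[[signal]][sub$wrist == "dominant"],
                      sub$child_id[sub$wrist == "dominant"])
  nd_blocks <- split(sub[[signal]][sub$wrist == "non_dominant"],
                     sub$child_id[sub$wrist == "non_dominant"])
  if (length(dom_blocks) == 0L || length(nd_blocks) == 0L) {
    abort_wc("activity '%s' lacks one wrist", activity)
  }
  q_dom <- sample_quantile(unlist(dom_blocks, use.names = FALSE), tau)
  q_nd <- sample_quantile(unlist(nd_blocks, use.names = FALSE), tau)
  point <- q_dom - q_nd

  reps <- withr::with_seed(cfg$seed, {
    vapply(seq_len(cfg$B), function(b) {
      draw <- sample(children, length(children), replace = TRUE)
      d <- unlist(dom_blocks[draw], use.names = FALSE)
      n <- unlist(nd_blocks[draw], use.names = FALSE)
      if (length(d) == 0L || length(n) == 0L) return(NA_real_)
      sample_quantile(d, tau) - sample_quantile(n, tau)
    }, numeric(1))
  })
  reps <- reps[is.finite(reps)]
  degenerate <- length(reps) < 2L || sd(reps) == 0
  zero_atom <- q_dom == 0 && q_nd == 0
  converged <- !degenerate && !zero_atom
  if (converged) {
    ci <- unname(quantile(reps, c(cfg$alpha / 2, 1 - cfg$alpha / 2), type = 7))
  } else {
    ci <- c(NA_real_, NA_real_)
  }
  tibble::tibble(
    activity = activity, tau = tau, diff = point,
    ci_low = ci[1], ci_high = ci[2], converged = converged,
    significant = converged && (ci[1] > 0 || ci[2] < 0)
  )
}

#' Quantile-contrast table across activities and levels
#'
#' Runs [clustered_bootstrap()] for every activity at the 25th, 50th and
#' 75th percentiles and assembles a descriptive table in the layout of the
#' calibration study's wrist-contrast results: per-wrist median (IQR) of
#' counts/5 s plus the contrast, CI, and convergence/significance flags at
#' each level.
#'
#' @inheritParams clustered_bootstrap
#' @param activities activity labels (default: all in the table).
#' @param taus quantile levels.
#' @return A tibble with one row per activity by tau.
#' @export
quantile_diff_table <- function(epochs, cfg = bootstrap_config(),
                                activities = NULL, taus = c(0.25, 0.5, 0.75),
                                signal = "axis1") {
  assert_epoch_table(epochs, need = c("child_id", "wrist", "activity", signal))
  activities <- activities %||% unique(epochs$activity)
  out <- list()
  for (a in activities) {
    sub <- dplyr::filter(epochs, .data$activity == !!a)
    if (nrow(sub) == 0L) {
      warning(sprintf("activity '%s' has no epochs after filtering; skipped", a),
              call. = FALSE)
      next
    }
    desc <- dplyr::summarise(
      dplyr::group_by(sub, .data$wrist),
      q25 = sample_quantile(.data[[signal]], 0.25),
      q50 = sample_quantile(.data[[signal]], 0.50),
      q75 = sample_quantile(.data[[signal]], 0.75),
      .groups = "drop")
    n_children <- length(unique(sub$child_id))
    for (tau in taus) {
      row <- clustered_bootstrap(epochs, a, tau, cfg, signal)
      row$n_children <- n_children
      for (w in WRISTS) {
        pre <- if (w == "dominant") "dom" else "nd"
        for (q in c("q25", "q50", "q75")) {
          row[[paste(pre, q, sep = "_")]] <- desc[[q]][desc$wrist == w]
        }
      }
      out[[length(out) + 1L]] <- row
    }
  }
  dplyr::bind_rows(out)
}
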
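# Independent oracles, deliberately written without the package's code paths.

# type-7 quantile by hand: position (n-1)*tau, linear interpolation
quantile7_oracle <- function(x, tau) {
  x <- sort(x)
  h <- (length(x) - 1) * tau
  lo <- floor(h) + 1
  hi <- ceiling(h) + 1
  x[lo] + (h - (lo - 1)) * (x[hi] - x[lo])
}

# AUC by brute force over all cross-pairs, ties counted one half
auc_allpairs_oracle <- function(sed, light) {
  g <- outer(light, sed, function(l, s) (l > s) + 0.5 * (l == s))
  mean(g)
}

# Youden threshold by exhaustive scan over candidates with the stated
# tie-break (smallest threshold attaining the maximum)
youden_scan_oracle <- function(sed, light) {
  cand <- sort(unique(c(sed, light)))
  cand <- c(cand, max(cand) + 1)
  best <- -Inf; best_t <- NA
  for (t in cand) {
    j <- mean(light >= t) * 100 + mean(sed < t) * 100
    if (j > best + 1e-9) { best <- j; best_t <- t }
  }
  list(threshold = best_t, j = best)
}

# numeric inversion of the ZILN mixture CDF (independent of the package's
# closed-form quantile function)
ziln_cdf_invert_oracle <- function(pi, mu, sigma, tau) {
  if (tau <= pi) return(0)
  cdf <- function(x) pi + (1 - pi) * plnorm(x, mu, sigma)
  stats::uniroot(function(x) cdf(x) - tau, c(1e-12, 1e9), tol = 1e-10)$root
}

# small labeled two-wrist epoch table from raw count vectors
toy_epochs <- function(dom, nd, activity = "Task", n_children = 2) {
  stopifnot(length(dom) %% n_children == 0, length(nd) %% n_children == 0)
  mk <- function(x, w) tibble::tibble(
    child_id = rep(sprintf("c%02d", seq_len(n_children)),
                   each = length(x) / n_children),
    wrist = w, activity = activity,
    epoch_index = rep(seq_len(length(x) / n_children) - 1L, n_children),
    axis1 = as.integer(x), axis2 = 0L, axis3 = 0L)
  dplyr::bind_rows(mk(dom, "dominant"), mk(nd, "non_dominant"))
}
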
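#' Zero-inflated lognormal parameters
#'
#' Container for the three-parameter zero-inflated lognormal (ZILN)
#' distribution used to emulate per-activity accelerometer count
#' distributions: a point mass `pi` at exactly zero counts plus a lognormal
#' positive part with log-scale location `mu` and spread `sigma`.
#'
#' The quantile function is
#' \deqn{Q(\tau) = 0 \textrm{ for } \tau \le \pi, \quad
#'       Q(\tau) = \exp\{\mu + \sigma \, \Phi^{-1}((\tau-\pi)/(1-\pi))\}
#'       \textrm{ otherwise,}}
#' which is non-decreasing in \eqn{\tau}.
#'
#' @param pi probability mass at zero, in `[0, 1)`.
#' @param mu log-scale location of the positive part.
#' @param sigma log-scale spread of the positive part, `>= 0` (`sigma = 0`
#'   denotes a degenerate positive part concentrated at `exp(mu)`).
#' @return An object of class `ziln_params`.
#' @seealso [fit_ziln()], [ziln_quantile()]
#' @export
ziln_params <- function(pi, mu, sigma) {
  assert_scalar_number(pi, "pi", lower = 0, upper = 1 - 1e-12)
  assert_scalar_number(mu, "mu")
  assert_scalar_number(sigma, "sigma", lower = 0)
  structure(list(pi = pi, mu = mu, sigma = sigma), class = "ziln_params")
}

#' @export
print.ziln_params <- function(x, ...) {
  cat(sprintf("<ziln_params> pi=%.6g mu=%.6g sigma=%.6g (median %.6g)\n",
              x$pi, x$mu, x$sigma, ziln_quantile(x, 0.5)))
  invisible(x)
}

#' ZILN quantile function
#'
#' @param params a [ziln_params()] object.
#' @param tau vector of probabilities in `[0, 1]`.
#' @return Quantiles on the counts scale (real-valued; zero for
#'   `tau <= pi`).
#' @export
ziln_quantile <- function(params, tau) {
  stopifnot(inherits(params, "ziln_params"))
  if (any(!is.finite(tau)) || any(tau < 0) || any(tau > 1)) {
    abort_wc("`tau` must lie in [0, 1]")
  }
  out <- numeric(length(tau))
  pos <- tau > params$pi
  if (any(pos)) {
    a <- (tau[pos] - params$pi) / (1 - params$pi)
    out[pos] <- exp(params$mu + params$sigma * qnorm(a))
  }
  out
}

# closed-form (mu, sigma) through two positive quantiles at a given pi
.ziln_musigma <- function(pi, q50, q75) {
  z50 <- qnorm((0.50 - pi) / (1 - pi))
  z75 <- qnorm((0.75 - pi) / (1 - pi))
  if (q75 > q50) {
    sigma <- (log(q75) - log(q50)) / (z75 - z50)
    mu <- log(q50) - sigma * z50
  } else {
    # degenerate positive part: all mass of the positive tail at q50
    sigma <- 0
    mu <- log(q50)
  }
  list(mu = mu, sigma = sigma)
}

#' Fit a zero-inflated lognormal to a quantile triple
#'
#' Matches the 25th/50th/75th percentiles of a ZILN distribution to a target
#' triple, as used to emulate the published median/IQR of counts per 5-s
#' epoch for one activity on one wrist.
#'
#' Matching conventions for under-identified (zero-containing) triples:
#' \itemize{
#'   \item `q25 = q50 = q75 = 0`: `pi = 0.75`, `mu = log(1)`, `sigma = 0.5`
#'     (the triple carries no information about the positive tail).
#'   \item `q50 = 0, q75 > 0`: `pi = 0.5`; `sigma` is taken from
#'     `sigma_fallback` (typically the fit of the opposite wrist for the
#'     same activity) or 1 if absent, and `mu = log(q75)` (the 75th
#'     percentile pins the positive-part median in this configuration).
#'   \item `q25 = 0, q50 > 0`: `pi = 0.25`, `(mu, sigma)` solved in closed
#'     form from `q50` and `q75`.
#'   \item all positive: `pi` is found in `[0, 0.25)` by root finding
#'     (tolerance 1e-9), with `(mu, sigma)` solved in closed form from
#'     `q50`/`q75` at each candidate `pi`, so that `Q(0.25)` matches `q25`.
#' }
#'
#' @param q25,q50,q75 target quantiles, counts per epoch, with
#'   `0 <= q25 <= q50 <= q75`.
#' @param sigma_fallback optional positive-part `sigma` used when the triple
#'   pins down only `q75` (see above).
#' @return A [ziln_params()] object whose quantile function reproduces every
#'   positive target to relative accuracy 1e-6.
#' @export
#' @examples
#' p <- fit_ziln(195, 357, 602)   # slow-walking counts, non-dominant wrist
#' ziln_quantile(p, c(0.25, 0.5, 0.75))
fit_ziln <- function(q25, q50, q75, sigma_fallback = NULL) {
  for (nm in c("q25", "q50", "q75")) {
    assert_scalar_number(get(nm), nm, lower = 0)
  }
  if (q25 > q50 || q50 > q75) {
    abort_wc("infeasible quantile triple (%s, %s, %s): must be non-decreasing",
             q25, q50, q75)
  }

  if (q75 == 0) {
    return(ziln_params(0.75, log(1), 0.5))
  }
  if (q50 == 0) {
    sigma <- sigma_fallback %||% 1.0
    assert_scalar_number(sigma, "sigma_fallback", lower = 0)
    # Q(0.75) = exp(mu + sigma * qnorm(0.5)) = exp(mu) when pi = 0.5
    return(ziln_params(0.5, log(q75), sigma))
  }
  if (q25 == 0) {
    ms <- .ziln_musigma(0.25, q50, q75)
    return(ziln_params(0.25, ms$mu, ms$sigma))
  }

  # all three positive: 1-D root for pi in [0, 0.25)
  gap <- function(pi) {
    ms <- .ziln_musigma(pi, q50, q75)
    ms$mu + ms$sigma * qnorm((0.25 - pi) / (1 - pi)) - log(q25)
  }
  if (abs(gap(0)) < 1e-12) {
    pi_hat <- 0
  } else if (gap(0) < 0) {
    abort_wc(paste0("quantile triple (%s, %s, %s) has a left tail lighter ",
                    "than any zero-inflated lognormal through its upper ",
                    "quantiles"), q25, q50, q75)
  } else {
    pi_hat <- tryCatch(
      uniroot(gap, c(0, 0.25 - 1e-9), tol = 1e-12)$root,
      error = function(e) {
        abort_wc("no zero-inflation in [0, 0.25) matches triple (%s, %s, %s)",
                 q25, q50, q75)
      }
    )
  }
  ms <- .ziln_musigma(pi_hat, q50, q75)
  fit <- ziln_params(pi_hat, ms$mu, ms$sigma)

  targets <- c(q25, q50, q75)
  got <- ziln_quantile(fit, c(0.25, 0.5, 0.75))
  relerr <- abs(got - targets) / pmax(targets, 1)
  if (any(targets > 0 & relerr > 1e-6)) {
    abort_wc("internal: ZILN fit failed to reproduce (%s, %s, %s)",
             q25, q50, q75)
  }
  fit
}
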
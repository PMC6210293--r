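#' Generator configuration
#'
#' Bundles every knob of the synthetic cohort generator: cohort size, epochs
#' per activity (5-s epochs; 60 epochs = the 5-min activity bouts of the
#' calibration protocol), the activity profile table, the probability that a
#' seated child-by-activity session is contaminated by standing/stepping,
#' the child-level random-effect spread, handedness mix, and the seed.
#'
#' @param n_children number of children (>= 2).
#' @param epochs_per_activity 5-s epochs per child per activity (>= 1).
#' @param activities profile table as from [default_activity_profiles()].
#' @param p_stand probability in `[0, 1)` that a seated child-by-activity
#'   session contains a contiguous run of walking-distributed epochs (the
#'   child stood up); such sessions are flagged unverified in the
#'   observation log. `p_stand = 1` is admitted so that a fully contaminated
#'   cohort can be simulated deliberately.
#' @param child_effect_sd log-scale SD of the per-child multiplicative
#'   random effect (shared across both wrists and all activities).
#' @param handedness_right proportion of right-dominant children.
#' @param seed integer seed; every draw of the generator flows from it.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(n_children = 167L,
                             epochs_per_activity = 60L,
                             activities = default_activity_profiles(),
                             p_stand = 0.05,
                             child_effect_sd = 0.3,
                             handedness_right = 0.9,
                             seed = 20180926L) {
  n_children <- assert_count(n_children, "n_children", lower = 2L)
  epochs_per_activity <- assert_count(epochs_per_activity, "epochs_per_activity")
  assert_scalar_number(p_stand, "p_stand", lower = 0, upper = 1)
  assert_scalar_number(child_effect_sd, "child_effect_sd", lower = 0)
  assert_scalar_number(handedness_right, "handedness_right", lower = 0, upper = 1)
  seed <- assert_count(seed, "seed", lower = 0L)
  if (!is.data.frame(activities) || nrow(activities) == 0) {
    abort_wc("`activities` must be a non-empty profile table")
  }
  assert_epoch_table(activities,
                     need = c("activity", "posture", "dom_q25", "dom_q50",
                              "dom_q75", "nd_q25", "nd_q50", "nd_q75", "rho",
                              "axis_ratio2", "axis_ratio3"))
  structure(list(n_children = n_children,
                 epochs_per_activity = epochs_per_activity,
                 activities = activities, p_stand = p_stand,
                 child_effect_sd = child_effect_sd,
                 handedness_right = handedness_right, seed = seed),
            class = "generator_config")
}

# within-child lognormal spread after removing the shared child effect, so
# the population marginal (child effect integrated out) matches the fit
.sigma_within <- function(sigma, child_effect_sd) {
  if (child_effect_sd > sigma) {
    warning(sprintf(paste0("child_effect_sd (%.3g) exceeds the fitted sigma ",
                           "(%.3g); within-child spread clamped to 0"),
                    child_effect_sd, sigma), call. = FALSE)
  }
  sqrt(max(sigma^2 - child_effect_sd^2, 0))
}

# vectorised ZILN quantile on probabilities u, given within-child sigma
.ziln_q_vec <- function(u, pi, mu, sigma_w) {
  out <- numeric(length(u))
  pos <- u > pi
  if (any(pos)) {
    out[pos] <- exp(mu + sigma_w * qnorm((u[pos] - pi) / (1 - pi)))
  }
  out
}

# Generate one activity for a fixed set of children using the current RNG
# state. `child_effects` is the shared per-child multiplicative effect.
.gen_activity <- function(profile, child_ids, child_effects, epochs,
                          child_effect_sd, axis_noise_sd = 0.2) {
  fits <- fit_profile(profile)
  n_children <- length(child_ids)
  n <- n_children * epochs
  ce <- rep(child_effects, each = epochs)

  z1 <- rnorm(n)
  z2 <- profile$rho * z1 + sqrt(1 - profile$rho^2) * rnorm(n)
  u <- list(dominant = pnorm(z1), non_dominant = pnorm(z2))
  # all-zero published triples denote no recorded movement: structural zeros
  zero_row <- list(dominant = profile$dom_q75 == 0,
                   non_dominant = profile$nd_q75 == 0)

  out <- vector("list", 2L)
  for (i in seq_along(WRISTS)) {
    w <- WRISTS[i]
    f <- fits[[w]]
    if (zero_row[[w]]) {
      x <- numeric(n)
    } else {
      sw <- .sigma_within(f$sigma, child_effect_sd)
      x <- .ziln_q_vec(u[[w]], f$pi, f$mu, sw) * ce
    }
    noise2 <- exp(rnorm(n, 0, axis_noise_sd))
    noise3 <- exp(rnorm(n, 0, axis_noise_sd))
    pos <- x > 0
    out[[i]] <- tibble::tibble(
      child_id = rep(child_ids, each = epochs),
      wrist = w,
      activity = profile$activity,
      epoch_index = rep(seq_len(epochs) - 1L, times = n_children),
      axis1 = as.integer(round(x)),
      axis2 = as.integer(round(ifelse(pos, x * profile$axis_ratio2 * noise2, 0))),
      axis3 = as.integer(round(ifelse(pos, x * profile$axis_ratio3 * noise3, 0)))
    )
  }
  dplyr::bind_rows(out)
}

#' Generate epoch counts for one activity profile
#'
#' Draws paired dominant/non-dominant 5-s epoch count series for
#' `n_children` children from the ZILN marginals fitted to the profile's
#' quantile targets, coupled across wrists by a Gaussian copula with the
#' profile's `rho`. A shared per-child multiplicative lognormal effect
#' induces within-child clustering; the within-child spread is deflated so
#' that the population marginal still matches the fitted targets after the
#' child effect is integrated out. Axes 2 and 3 are the axis-1 draw scaled
#' by the profile's ratios with independent multiplicative noise; all counts
#' are rounded to non-negative integers.
#'
#' @param profile a one-row profile table (see [activity_profile()]).
#' @param n_children,epochs cohort size and epochs per child (>= 1).
#' @param child_effect_sd log-scale SD of the per-child effect; 0 removes
#'   clustering.
#' @param seed optional integer seed (local to this call).
#' @return A tibble of epoch records: `child_id`, `wrist`, `activity`,
#'   `epoch_index`, `axis1`, `axis2`, `axis3`.
#' @export
#' @examples
#' walking <- dplyr::filter(default_activity_profiles(), activity == "Walking")
#' x <- generate_counts(walking, n_children = 5, epochs = 20, seed = 1)
generate_counts <- function(profile, n_children, epochs, child_effect_sd = 0,
                            seed = NULL) {
  n_children <- assert_count(n_children, "n_children")
  epochs <- assert_count(epochs, "epochs")
  assert_scalar_number(child_effect_sd, "child_effect_sd", lower = 0)
  stopifnot(is.data.frame(profile), nrow(profile) == 1L)
  gen <- function() {
    ids <- sprintf("c%04d", seq_len(n_children))
    ce <- exp(rnorm(n_children, 0, child_effect_sd))
    .gen_activity(profile, ids, ce, epochs, child_effect_sd)
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Generate a full synthetic cohort with an observation log
#'
#' Produces one epoch series per child by activity by wrist under a
#' [generator_config()], plus the direct-observation log the downstream
#' inclusion filter consumes. With probability `p_stand`, a seated
#' child-by-activity session is contaminated: a contiguous run (10--50% of
#' the bout) of walking-distributed epochs replaces the seated epochs on
#' both wrists, and the log entry is flagged `seated_verified = FALSE`.
#' Identical seeds reproduce the dataset exactly.
#'
#' @param config a [generator_config()].
#' @return A list with `epochs` (tibble of epoch records), `log` (tibble:
#'   `child_id`, `activity`, `seated_verified`, `completed`), and `children`
#'   (tibble: `child_id`, `handedness`, `child_effect`).
#' @export
generate_dataset <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  withr::with_seed(config$seed, {
    n <- config$n_children
    ids <- sprintf("c%04d", seq_len(n))
    handedness <- ifelse(runif(n) < config$handedness_right, "right", "left")
    ce <- exp(rnorm(n, 0, config$child_effect_sd))

    profiles <- config$activities
    walking <- profiles[profiles$posture == "walking", ]
    if (config$p_stand > 0 && nrow(walking) == 0) {
      abort_wc("p_stand > 0 requires a walking profile for contamination draws")
    }
    epochs_list <- vector("list", nrow(profiles))
    log_list <- vector("list", nrow(profiles))
    e <- config$epochs_per_activity

    for (a in seq_len(nrow(profiles))) {
      prof <- profiles[a, ]
      tab <- .gen_activity(prof, ids, ce, e, config$child_effect_sd)
      contaminated <- rep(FALSE, n)
      if (prof$posture == "seated" && config$p_stand > 0) {
        contaminated <- runif(n) < config$p_stand
        for (ci in which(contaminated)) {
          lo <- max(1L, as.integer(round(0.1 * e)))
          hi <- min(e, max(lo, as.integer(round(0.5 * e))))
          len <- if (hi > lo) sample(lo:hi, 1L) else lo
          start <- sample.int(e - len + 1L, 1L)
          run <- .gen_activity(walking[1, ], ids[ci], ce[ci], len,
                               config$child_effect_sd)
          idx <- tab$child_id == ids[ci] &
            tab$epoch_index >= (start - 1L) & tab$epoch_index < (start - 1L + len)
          for (col in c("axis1", "axis2", "axis3")) {
            tab[[col]][idx & tab$wrist == "dominant"] <-
              run[[col]][run$wrist == "dominant"]
            tab[[col]][idx & tab$wrist == "non_dominant"] <-
              run[[col]][run$wrist == "non_dominant"]
          }
        }
      }
      epochs_list[[a]] <- tab
      log_list[[a]] <- tibble::tibble(
        child_id = ids, activity = prof$activity,
        seated_verified = if (prof$posture == "seated") !contaminated else TRUE,
        completed = TRUE
      )
    }
    list(epochs = dplyr::bind_rows(epochs_list),
         log = dplyr::bind_rows(log_list),
         children = tibble::tibble(child_id = ids, handedness = handedness,
                                   child_effect = ce))
  })
}
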
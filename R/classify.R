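#' Published wrist cut-points for sedentary time in 5--11-year-olds
#'
#' The cut-point thresholds (counts/5 s) derived by the wrist-placement
#' calibration study this package models, for each signal and wrist, using
#' the ActiGraph GT3X+ in 5-s epochs. Counts at or above the threshold are
#' classified light-or-above; counts below it, sedentary.
#'
#' @return A tibble with columns `signal`, `wrist`, `cutpoint`.
#' @export
#' @examples
#' wrist_sedentary_cutpoints()
wrist_sedentary_cutpoints <- function() {
  tibble::tribble(
    ~signal, ~wrist,         ~cutpoint,
    "axis1", "non_dominant", 203,
    "axis1", "dominant",     229,
    "axis2", "non_dominant", 200,
    "axis2", "dominant",     220,
    "axis3", "non_dominant", 201,
    "axis3", "dominant",     219,
    "vm",    "non_dominant", 397,
    "vm",    "dominant",     428
  )
}

#' Look up a packaged cut-point
#'
#' @param signal one of `axis1`, `axis2`, `axis3`, `vm`.
#' @param wrist `"dominant"` or `"non_dominant"`.
#' @return The threshold in counts/5 s.
#' @export
get_cutpoint <- function(signal = "axis1", wrist = "non_dominant") {
  assert_wrist(wrist)
  tab <- wrist_sedentary_cutpoints()
  hit <- tab$cutpoint[tab$signal == signal & tab$wrist == wrist]
  if (length(hit) != 1L) abort_wc("no packaged cut-point for %s/%s", signal, wrist)
  hit
}

#' Classify epochs as sedentary or light-or-above
#'
#' Applies the boundary convention of the Youden threshold derivation:
#' `count < cutpoint` is sedentary, `count >= cutpoint` is light-or-above.
#'
#' @param series numeric vector of per-epoch counts (counts/5 s).
#' @param cutpoint positive count threshold.
#' @return A factor with levels `sedentary`, `light_plus`.
#' @export
#' @examples
#' classify_epochs(c(0, 150, 202, 203, 500), 203)
classify_epochs <- function(series, cutpoint) {
  assert_scalar_number(cutpoint, "cutpoint", lower = 1e-12)
  if (length(series) == 0L) abort_wc("`series` must be non-empty")
  factor(ifelse(series >= cutpoint, "light_plus", "sedentary"),
         levels = c("sedentary", "light_plus"))
}

#' Summarize classified epochs into minutes by intensity
#'
#' @param labels factor from [classify_epochs()].
#' @param epoch_seconds epoch length in seconds (5 throughout the
#'   calibration protocol).
#' @return A one-row tibble: `minutes_sedentary`, `minutes_light_plus`,
#'   `total_minutes`, `epochs_classified`. Minutes are exact
#'   (`count * epoch_seconds / 60`), so the two classes always sum to the
#'   total.
#' @export
summarize_intensity <- function(labels, epoch_seconds = 5) {
  if (length(labels) == 0L) abort_wc("`labels` must be non-empty")
  assert_scalar_number(epoch_seconds, "epoch_seconds", lower = 1e-12)
  n_sed <- sum(labels == "sedentary")
  n_light <- sum(labels == "light_plus")
  m_sed <- n_sed * epoch_seconds / 60
  m_light <- n_light * epoch_seconds / 60
  tibble::tibble(
    minutes_sedentary = m_sed,
    minutes_light_plus = m_light,
    total_minutes = m_sed + m_light,  # conservation holds exactly
    epochs_classified = n_sed + n_light
  )
}
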
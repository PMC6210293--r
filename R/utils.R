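#' @importFrom rlang .data %||%
#' @importFrom stats qnorm pnorm rnorm runif quantile sd median plnorm uniroot
#' @importFrom utils read.csv write.csv packageVersion
NULL

# stop() with call.=FALSE and sprintf-style formatting
abort_wc <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort_wc("`%s` must be a single finite number", name)
  }
  if (x < lower || x > upper) {
    abort_wc("`%s` must be in [%s, %s], got %s", name, lower, upper, x)
  }
  invisible(x)
}

assert_count <- function(x, name, lower = 1L) {
  assert_scalar_number(x, name, lower = lower)
  if (x != as.integer(x)) abort_wc("`%s` must be an integer, got %s", name, x)
  invisible(as.integer(x))
}

WRISTS <- c("dominant", "non_dominant")

assert_wrist <- function(wrist) {
  if (!is.character(wrist) || length(wrist) != 1L || !wrist %in% WRISTS) {
    abort_wc("`wrist` must be one of %s", paste(WRISTS, collapse = ", "))
  }
  wrist
}

EPOCH_COLS <- c("child_id", "wrist", "activity", "epoch_index",
                "axis1", "axis2", "axis3")

assert_epoch_table <- function(epochs, need = EPOCH_COLS) {
  missing <- setdiff(need, names(epochs))
  if (length(missing)) {
    abort_wc("epoch table lacks column(s): %s", paste(missing, collapse = ", "))
  }
  invisible(epochs)
}
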
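#' @name epoch-dialect
#' @title Epoch file dialect
#' @description
#' Epoch count files carry one child-by-wrist series. Two metadata header
#' lines precede a column-header row:
#' \preformatted{
#' # wristcal-epochs; child=c0001; wrist=dominant; device=GT3X+0001
#' # start=2018-07-02T09:00:00; epoch_seconds=5; delim=comma
#' epoch_index,axis1,axis2,axis3
#' 0,12,8,6
#' }
#' `delim` may be `comma` or `tab` and governs the body. Activity labels are
#' not stored in the file; a separate tab-separated schedule
#' (`child_id`, `wrist`, `activity`, `start_epoch`, `n_epochs`) maps epoch
#' ranges to activities, mirroring how activity bouts are timed against a
#' session plan rather than recorded by the device. Timestamps are metadata
#' only and ignored by analysis.
NULL

.parse_kv <- function(line, lineno) {
  line <- sub("^#\\s*", "", line)
  parts <- strsplit(line, ";\\s*")[[1]]
  kv <- list()
  for (p in parts) {
    eq <- regexpr("=", p, fixed = TRUE)
    if (eq < 0) next  # bare token (the file signature)
    kv[[substr(p, 1, eq - 1)]] <- trimws(substr(p, eq + 1, nchar(p)))
  }
  kv
}

#' Read one epoch count file
#'
#' Parses the dialect described in [epoch-dialect]. Malformed headers,
#' negative counts, and non-contiguous epoch indices raise errors naming
#' the offending line.
#'
#' @param path file path.
#' @return A tibble with `child_id`, `wrist`, `epoch_index`, `axis1`,
#'   `axis2`, `axis3` plus attributes `epoch_seconds`, `device`, `start`.
#' @export
read_epochs <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) < 3L) abort_wc("line 1: file too short for a valid header")
  if (!startsWith(lines[1], "# wristcal-epochs")) {
    abort_wc("line 1: missing 'wristcal-epochs' signature")
  }
  meta1 <- .parse_kv(lines[1], 1L)
  meta2 <- .parse_kv(lines[2], 2L)
  for (k in c("child", "wrist")) {
    if (is.null(meta1[[k]])) abort_wc("line 1: header lacks '%s'", k)
  }
  if (is.null(meta2$epoch_seconds)) abort_wc("line 2: header lacks 'epoch_seconds'")
  if (!meta1$wrist %in% WRISTS) abort_wc("line 1: unknown wrist '%s'", meta1$wrist)
  delim <- switch(meta2$delim %||% "comma",
                  comma = ",", tab = "\t",
                  abort_wc("line 2: unknown delim '%s'", meta2$delim))

  expect_cols <- c("epoch_index", "axis1", "axis2", "axis3")
  header <- strsplit(lines[3], delim, fixed = TRUE)[[1]]
  if (!identical(trimws(header), expect_cols)) {
    abort_wc("line 3: column header must be %s", paste(expect_cols, collapse = ","))
  }
  body <- lines[-(1:3)]
  body <- body[nzchar(trimws(body))]
  if (length(body) == 0L) {
    tab <- tibble::tibble(epoch_index = integer(), axis1 = integer(),
                          axis2 = integer(), axis3 = integer())
  } else {
    raw <- utils::read.table(text = body, sep = delim, col.names = expect_cols,
                             colClasses = "numeric")
    for (col in expect_cols) {
      bad <- which(!is.finite(raw[[col]]) | raw[[col]] != as.integer(raw[[col]]))
      if (length(bad)) abort_wc("line %d: non-integer %s", 3L + bad[1], col)
    }
    neg <- which(raw$axis1 < 0 | raw$axis2 < 0 | raw$axis3 < 0)
    if (length(neg)) abort_wc("line %d: negative count", 3L + neg[1])
    if (!identical(as.integer(raw$epoch_index), seq_len(nrow(raw)) - 1L)) {
      off <- which(as.integer(raw$epoch_index) != seq_len(nrow(raw)) - 1L)[1]
      abort_wc("line %d: epoch_index not contiguous from 0", 3L + off)
    }
    tab <- tibble::as_tibble(lapply(raw, as.integer))
  }
  out <- dplyr::mutate(tab, child_id = meta1$child, wrist = meta1$wrist,
                       .before = 1)
  attr(out, "epoch_seconds") <- as.numeric(meta2$epoch_seconds)
  attr(out, "device") <- meta1$device %||% NA_character_
  attr(out, "start") <- meta2$start %||% NA_character_
  out
}

#' Write one epoch count file
#'
#' Inverse of [read_epochs()]; write-then-read reproduces the counts
#' exactly.
#'
#' @param epochs tibble for a single child and wrist with `epoch_index`,
#'   `axis1`, `axis2`, `axis3` (plus `child_id`, `wrist` columns or
#'   explicit arguments).
#' @param path output path.
#' @param child_id,wrist series identity; defaults taken from the table.
#' @param device,start,epoch_seconds header metadata.
#' @param delim `"comma"` or `"tab"`.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path, child_id = NULL, wrist = NULL,
                         device = "GT3X+0000", start = "2018-07-02T09:00:00",
                         epoch_seconds = 5, delim = c("comma", "tab")) {
  delim <- match.arg(delim)
  infer <- function(x, default) {
    u <- unique(x)
    if (length(u) == 0L) default else u
  }
  child_id <- child_id %||% infer(epochs$child_id, "c0000")
  wrist <- wrist %||% infer(epochs$wrist, "dominant")
  if (length(child_id) != 1L || length(wrist) != 1L) {
    abort_wc("write_epochs() takes one child-by-wrist series per file")
  }
  sep <- if (delim == "comma") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("# wristcal-epochs; child=%s; wrist=%s; device=%s",
            child_id, wrist, device),
    sprintf("# start=%s; epoch_seconds=%s; delim=%s", start, epoch_seconds, delim),
    paste(c("epoch_index", "axis1", "axis2", "axis3"), collapse = sep)
  ), con)
  if (nrow(epochs)) {
    body <- do.call(paste, c(unname(epochs[c("epoch_index", "axis1",
                                             "axis2", "axis3")]), sep = sep))
    writeLines(body, con)
  }
  invisible(path)
}

#' Write / read a whole cohort as a file-per-series directory
#'
#' `write_epoch_dataset()` lays a labeled epoch table out as one epoch file
#' per child and wrist (activities concatenated in table order, epoch
#' indices renumbered per file), an activity `schedule.tsv`, and the
#' observation log `observation_log.tsv`. `read_epoch_dataset()` inverts
#' it, restoring per-activity epoch indices from the schedule.
#'
#' @param epochs labeled epoch table.
#' @param log observation log tibble.
#' @param dir output directory (created if needed).
#' @return `write_epoch_dataset()`: the directory, invisibly;
#'   `read_epoch_dataset()`: a list with `epochs` and `log`.
#' @export
write_epoch_dataset <- function(epochs, log, dir) {
  assert_epoch_table(epochs)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  sched <- list()
  keys <- dplyr::distinct(epochs, .data$child_id, .data$wrist)
  for (i in seq_len(nrow(keys))) {
    sub <- dplyr::filter(epochs, .data$child_id == keys$child_id[i],
                         .data$wrist == keys$wrist[i])
    r <- rle(sub$activity)  # keep the on-disk concatenation order
    runs <- tibble::tibble(activity = r$values, n_epochs = r$lengths)
    runs$start_epoch <- cumsum(dplyr::lag(runs$n_epochs, default = 0L))
    sched[[i]] <- dplyr::mutate(runs, child_id = keys$child_id[i],
                                wrist = keys$wrist[i])
    flat <- dplyr::mutate(sub, epoch_index = seq_len(nrow(sub)) - 1L)
    write_epochs(flat, file.path(dir, sprintf("%s_%s.csv", keys$child_id[i],
                                              keys$wrist[i])))
  }
  sched <- dplyr::bind_rows(sched)[, c("child_id", "wrist", "activity",
                                       "start_epoch", "n_epochs")]
  utils::write.table(sched, file.path(dir, "schedule.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  write_observation_log(log, file.path(dir, "observation_log.tsv"))
  invisible(dir)
}

#' @rdname write_epoch_dataset
#' @export
read_epoch_dataset <- function(dir) {
  sched <- tibble::as_tibble(utils::read.delim(file.path(dir, "schedule.tsv")))
  out <- list()
  keys <- dplyr::distinct(sched, .data$child_id, .data$wrist)
  for (i in seq_len(nrow(keys))) {
    tab <- read_epochs(file.path(dir, sprintf("%s_%s.csv", keys$child_id[i],
                                              keys$wrist[i])))
    runs <- dplyr::filter(sched, .data$child_id == keys$child_id[i],
                          .data$wrist == keys$wrist[i])
    tab$activity <- NA_character_
    tab$local_index <- NA_integer_
    for (j in seq_len(nrow(runs))) {
      idx <- tab$epoch_index >= runs$start_epoch[j] &
        tab$epoch_index < runs$start_epoch[j] + runs$n_epochs[j]
      tab$activity[idx] <- runs$activity[j]
      tab$local_index[idx] <- seq_len(sum(idx)) - 1L
    }
    if (anyNA(tab$activity)) {
      abort_wc("schedule does not cover every epoch of %s/%s",
               keys$child_id[i], keys$wrist[i])
    }
    tab$epoch_index <- tab$local_index
    tab$local_index <- NULL
    out[[i]] <- tab
  }
  epochs <- dplyr::bind_rows(out)[, EPOCH_COLS]
  list(epochs = epochs,
       log = read_observation_log(file.path(dir, "observation_log.tsv")))
}

#' Read / write the direct-observation log
#'
#' Tab-separated, one row per child-by-activity: `child_id`, `activity`,
#' `seated_verified`, `completed`.
#'
#' @param log observation log tibble.
#' @param path file path.
#' @export
write_observation_log <- function(log, path) {
  utils::write.table(log[, c("child_id", "activity", "seated_verified",
                             "completed")],
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_observation_log
#' @export
read_observation_log <- function(path) {
  tab <- tibble::as_tibble(utils::read.delim(path))
  tab$seated_verified <- as.logical(tab$seated_verified)
  tab$completed <- as.logical(tab$completed)
  tab
}

#' Re-integrate an epoch count series to a longer epoch length
#'
#' Sums each `factor` consecutive input epochs into one output epoch (e.g.
#' 1-s exports re-integrated to 5-s epochs). A trailing remainder shorter
#' than `factor` is dropped with a warning; total counts are otherwise
#' conserved.
#'
#' @param series numeric vector of per-epoch counts.
#' @param factor positive integer number of input epochs per output epoch.
#' @return Numeric vector of length `floor(length(series) / factor)`.
#' @export
#' @examples
#' reintegrate(c(1, 2, 3, 4, 5), 5)  # 15
reintegrate <- function(series, factor) {
  factor <- assert_count(factor, "factor")
  n_out <- length(series) %/% factor
  dropped <- length(series) - n_out * factor
  if (dropped > 0) {
    warning(sprintf("dropping %d trailing epoch(s) not filling a window",
                    dropped), call. = FALSE)
  }
  if (n_out == 0L) return(numeric(0))
  colSums(matrix(series[seq_len(n_out * factor)], nrow = factor))
}

#' Vector magnitude of triaxial counts
#'
#' Euclidean norm of the three axis counts within an epoch, kept
#' real-valued (no rounding).
#'
#' @param axis1,axis2,axis3 non-negative count vectors.
#' @return Numeric vector `sqrt(axis1^2 + axis2^2 + axis3^2)`.
#' @export
vector_magnitude <- function(axis1, axis2, axis3) {
  if (any(axis1 < 0 | axis2 < 0 | axis3 < 0, na.rm = TRUE)) {
    abort_wc("axis counts must be non-negative")
  }
  sqrt(axis1^2 + axis2^2 + axis3^2)
}

#' Add a vector-magnitude column to an epoch table
#'
#' @param epochs epoch table with `axis1`, `axis2`, `axis3`.
#' @return The table with a real-valued `vm` column.
#' @export
add_vm <- function(epochs) {
  dplyr::mutate(epochs, vm = vector_magnitude(.data$axis1, .data$axis2,
                                              .data$axis3))
}

#' Apply the direct-observation inclusion filter
#'
#' Removes every epoch of any seated child-by-activity session whose log
#' entry is not verified seated or not completed, on both wrists. Other
#' activities of the same child are retained, and light-intensity
#' activities (walking) are retained regardless of seated flags —
#' mirroring per-activity (not per-child) exclusion. Filtering is
#' idempotent.
#'
#' @param epochs labeled epoch table.
#' @param log observation log with one entry per child-by-activity.
#' @param light_activities activity labels that are not seated.
#' @return The filtered epoch table.
#' @export
apply_observation_filter <- function(epochs, log,
                                     light_activities = "Walking") {
  assert_epoch_table(epochs)
  keys <- dplyr::distinct(epochs, .data$child_id, .data$activity)
  unmatched <- dplyr::anti_join(keys, log, by = c("child_id", "activity"))
  if (nrow(unmatched)) {
    abort_wc("no observation-log entry for %d epoch series (first: %s / %s)",
             nrow(unmatched), unmatched$child_id[1], unmatched$activity[1])
  }
  flags <- dplyr::transmute(log, .data$child_id, .data$activity,
                            .keep_row = .data$seated_verified & .data$completed)
  out <- dplyr::left_join(epochs, flags, by = c("child_id", "activity"))
  out <- dplyr::filter(out, .data$activity %in% light_activities | .data$.keep_row)
  dplyr::select(out, -".keep_row")
}
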
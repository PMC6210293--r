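#' Pipeline configuration
#'
#' Bundles the stage configurations of the full analysis: simulate a
#' cohort, apply the observation filter, contrast wrists at the three
#' quartiles, calibrate cut-points, and classify epoch streams.
#'
#' @param generator a [generator_config()].
#' @param bootstrap a [bootstrap_config()].
#' @param calibration a [calibration_config()].
#' @param output_dir directory for stage outputs.
#' @param log_level `"info"` or `"quiet"`.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = generator_config(),
                            bootstrap = bootstrap_config(),
                            calibration = calibration_config(),
                            output_dir = "wristcal_output",
                            log_level = c("info", "quiet")) {
  stopifnot(inherits(generator, "generator_config"),
            inherits(bootstrap, "bootstrap_config"),
            inherits(calibration, "calibration_config"))
  structure(list(generator = generator, bootstrap = bootstrap,
                 calibration = calibration, output_dir = output_dir,
                 log_level = match.arg(log_level)),
            class = "pipeline_config")
}

#' Derive all stage seeds from one master seed
#'
#' @param config a [pipeline_config()].
#' @param seed master integer seed.
#' @return The config with generator, bootstrap and calibration seeds set
#'   to `seed`, `seed + 1`, `seed + 2`.
#' @export
set_pipeline_seed <- function(config, seed) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- assert_count(seed, "seed", lower = 0L)
  config$generator$seed <- seed
  config$bootstrap$seed <- seed + 1L
  config$calibration$seed <- seed + 2L
  config
}

#' Read a pipeline configuration from YAML
#'
#' Every field of every stage config may be given; omitted fields keep
#' package defaults. Activity profiles may be overridden with a list of
#' `{activity, posture, dominant, non_dominant, rho, axis_ratio2,
#' axis_ratio3}` entries.
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  acts <- default_activity_profiles()
  if (!is.null(y$generator$activities)) {
    acts <- dplyr::bind_rows(lapply(y$generator$activities, function(a) {
      do.call(activity_profile, c(
        list(activity = a$activity, posture = a$posture,
             dominant = as.numeric(a$dominant),
             non_dominant = as.numeric(a$non_dominant)),
        a[intersect(names(a), c("rho", "axis_ratio2", "axis_ratio3"))]))
    }))
  }
  g <- y$generator %||% list()
  gen <- generator_config(
    n_children = g$n_children %||% 167L,
    epochs_per_activity = g$epochs_per_activity %||% 60L,
    activities = acts,
    p_stand = g$p_stand %||% 0.05,
    child_effect_sd = g$child_effect_sd %||% 0.3,
    handedness_right = g$handedness_right %||% 0.9,
    seed = g$seed %||% 20180926L)
  b <- y$bootstrap %||% list()
  bs <- bootstrap_config(B = b$B %||% 100L, alpha = b$alpha %||% 0.05,
                         seed = b$seed %||% 20180926L)
  cc <- y$calibration %||% list()
  cal <- calibration_config(
    k = cc$k %||% 10L,
    calibration_fraction = cc$calibration_fraction %||% (100 / 167),
    seed = cc$seed %||% 20180926L,
    signals = cc$signals %||% c("axis1", "axis2", "axis3", "vm"),
    mode = cc$mode %||% "cv", eval = cc$eval %||% "out_of_fold",
    pooled_sedentary = cc$pooled_sedentary %||% FALSE,
    validation_B = cc$validation_B %||% 200L)
  pipeline_config(gen, bs, cal,
                  output_dir = y$output_dir %||% "wristcal_output",
                  log_level = y$log_level %||% "info")
}

.write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", row.names = FALSE, quote = FALSE)
  path
}

#' Run the full calibration pipeline
#'
#' Simulates a cohort, applies the direct-observation filter, estimates
#' wrist quantile contrasts with clustered bootstrap CIs, calibrates
#' cut-points per wrist and signal, classifies each wrist's filtered epoch
#' stream with its derived axis-1 cut-point, and writes every table plus a
#' run manifest to `config$output_dir`. Re-running with the same config is
#' byte-identical. Any stage error removes the partial outputs and aborts
#' naming the stage.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the manifest and in-memory stage results.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) {
    if (config$log_level == "info") message(sprintf(...))
  }
  written <- character(0)
  stage <- "simulate"
  res <- tryCatch({
    say("[simulate] %d children x %d activities x %d epochs",
        config$generator$n_children, nrow(config$generator$activities),
        config$generator$epochs_per_activity)
    ds <- generate_dataset(config$generator)
    f <- file.path(config$output_dir, "epochs.tsv")
    written <- c(written, .write_tsv(ds$epochs, f))
    written <- c(written, write_observation_log(
      ds$log, file.path(config$output_dir, "observation_log.tsv")))

    stage <- "filter"
    light <- config$generator$activities$activity[
      config$generator$activities$posture == "walking"]
    filtered <- apply_observation_filter(ds$epochs, ds$log, light)
    say("[filter] %d of %d epochs retained", nrow(filtered), nrow(ds$epochs))

    stage <- "compare-quantiles"
    qt <- quantile_diff_table(filtered, config$bootstrap,
                              activities = config$generator$activities$activity)
    written <- c(written, .write_tsv(
      qt, file.path(config$output_dir, "quantile_differences.tsv")))

    stage <- "calibrate"
    cal <- calibrate_all(filtered, config$calibration,
                         light_activities = light)
    written <- c(written, .write_tsv(
      cal$results, file.path(config$output_dir, "cutpoints.tsv")))
    written <- c(written, .write_tsv(
      cal$folds, file.path(config$output_dir, "cutpoint_folds.tsv")))

    stage <- "classify"
    summaries <- list()
    for (w in WRISTS) {
      row <- cal$results[cal$results$wrist == w &
                           cal$results$signal == "axis1", ]
      cut_w <- if (nrow(row) == 1L) row$cutpoint else
        get_cutpoint("axis1", w)
      series <- filtered$axis1[filtered$wrist == w]
      labels <- classify_epochs(series, cut_w)
      s <- summarize_intensity(labels)
      summaries[[w]] <- dplyr::mutate(s, wrist = w, cutpoint = cut_w,
                                      .before = 1)
    }
    summaries <- dplyr::bind_rows(summaries)
    written <- c(written, .write_tsv(
      summaries, file.path(config$output_dir, "intensity_summary.tsv")))

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(packageVersion("wristcal")),
      seeds = list(generator = config$generator$seed,
                   bootstrap = config$bootstrap$seed,
                   calibration = config$calibration$seed),
      n_children = config$generator$n_children,
      files = lapply(stats::setNames(written, basename(written)),
                     function(p) list(md5 = unname(tools::md5sum(p)))))
    mf <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mf, auto_unbox = TRUE, pretty = TRUE)
    written <- c(written, mf)
    say("[done] %d files in %s", length(written), config$output_dir)
    list(manifest = manifest, dataset = ds, filtered = filtered,
         quantile_table = qt, calibration = cal, summaries = summaries,
         files = written)
  }, error = function(e) {
    unlink(written)
    abort_wc("pipeline failed at stage '%s': %s", stage, conditionMessage(e))
  })
  invisible(res)
}

# minimal --flag value parser for the CLI entry point
.parse_flags <- function(args) {
  out <- list(positional = character(0))
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (startsWith(a, "--")) {
      if (i == length(args) || startsWith(args[i + 1L], "--")) {
        out[[substring(a, 3)]] <- TRUE
        i <- i + 1L
      } else {
        out[[substring(a, 3)]] <- args[i + 1L]
        i <- i + 2L
      }
    } else {
      out$positional <- c(out$positional, a)
      i <- i + 1L
    }
  }
  out
}

#' Command-line entry point
#'
#' Thin dispatcher behind the `wristcal.R` script shipped in
#' `inst/scripts/`. Subcommands: `simulate` (write a synthetic cohort as
#' epoch dialect files), `filter`, `compare-quantiles`, `calibrate`,
#' `classify` (apply a cut-point to an epoch file), and `run-all` (the
#' full [run_pipeline()]). Common flags: `--config <yaml>`,
#' `--seed <int>`, `--output-dir <dir>`, `--mode {cv,repeats}`.
#'
#' @param args character vector of command-line arguments.
#' @return Exit status, invisibly (0 on success).
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: wristcal.R <simulate|filter|compare-quantiles|calibrate|",
    "        classify|run-all> [--config cfg.yaml] [--seed N]",
    "        [--output-dir DIR] [--mode cv|repeats]",
    "        classify: --epochs FILE --cutpoint N | --signal S --wrist W",
    sep = "\n")
  if (length(args) == 0L) { message(usage); return(invisible(1L)) }
  cmd <- args[1]
  fl <- .parse_flags(args[-1])
  cfg <- if (!is.null(fl$config)) read_pipeline_config(fl$config) else
    pipeline_config()
  if (!is.null(fl[["output-dir"]])) cfg$output_dir <- fl[["output-dir"]]
  if (!is.null(fl$mode)) cfg$calibration$mode <- fl$mode
  if (!is.null(fl$seed)) cfg <- set_pipeline_seed(cfg, as.integer(fl$seed))

  light <- cfg$generator$activities$activity[
    cfg$generator$activities$posture == "walking"]
  sim <- function() generate_dataset(cfg$generator)
  filt <- function(ds) apply_observation_filter(ds$epochs, ds$log, light)

  switch(cmd,
    "simulate" = {
      ds <- sim()
      write_epoch_dataset(ds$epochs, ds$log, cfg$output_dir)
      message(sprintf("wrote cohort to %s", cfg$output_dir))
    },
    "filter" = {
      ds <- sim()
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(filt(ds), file.path(cfg$output_dir, "epochs_filtered.tsv"))
    },
    "compare-quantiles" = {
      qt <- quantile_diff_table(filt(sim()), cfg$bootstrap,
                                activities = cfg$generator$activities$activity)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(qt, file.path(cfg$output_dir, "quantile_differences.tsv"))
    },
    "calibrate" = {
      cal <- calibrate_all(filt(sim()), cfg$calibration,
                           light_activities = light)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(cal$results, file.path(cfg$output_dir, "cutpoints.tsv"))
      .write_tsv(cal$folds, file.path(cfg$output_dir, "cutpoint_folds.tsv"))
    },
    "classify" = {
      if (is.null(fl$epochs)) abort_wc("classify needs --epochs FILE")
      tab <- read_epochs(fl$epochs)
      cut_use <- if (!is.null(fl$cutpoint)) as.numeric(fl$cutpoint) else
        get_cutpoint(fl$signal %||% "axis1", fl$wrist %||% unique(tab$wrist))
      labels <- classify_epochs(tab$axis1, cut_use)
      dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
      .write_tsv(dplyr::mutate(tab, label = as.character(labels)),
                 file.path(cfg$output_dir, "epoch_labels.tsv"))
      .write_tsv(dplyr::mutate(summarize_intensity(labels),
                               cutpoint = cut_use, .before = 1),
                 file.path(cfg$output_dir, "intensity_summary.tsv"))
    },
    "run-all" = { run_pipeline(cfg) },
    { message(usage); return(invisible(1L)) }
  )
  invisible(0L)
}
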
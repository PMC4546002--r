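# End-to-end orchestration and file I/O: simulate -> detect -> analyze,
# with deterministic seeding, manifests and a JSON analysis report.

#' Pipeline run configuration
#'
#' Bundles the simulation configuration with detection and analysis
#' parameters. Every stochastic stage derives its seed from `master_seed`.
#'
#' @param sim a [sim_config()].
#' @param quality_threshold gaze quality criterion (default 0.2).
#' @param penalty_c penalty constant for [select_penalty()].
#' @param min_samples segment discard threshold (samples).
#' @param edge_trim boundary samples excluded from segment velocity fits
#'   (see [classify_segments()]).
#' @param speed_threshold saccade speed threshold (deg/s).
#' @param n_bins direction histogram bins.
#' @param mass_fractions enclosed-mass fractions for the velocity HDR
#'   levels.
#' @param conf_level confidence level for all intervals.
#' @param master_seed overrides `sim$master_seed` when non-NULL.
#' @return object of class `run_config`.
#' @export
run_config <- function(sim = sim_config(), quality_threshold = 0.2,
                       penalty_c = 1.25, min_samples = 12, edge_trim = 3,
                       speed_threshold = 50, n_bins = 36,
                       mass_fractions = c(0.25, 0.5, 0.75),
                       conf_level = 0.95, master_seed = NULL) {
  if (!is.null(master_seed)) sim$master_seed <- master_seed
  structure(list(sim = sim, quality_threshold = quality_threshold,
                 penalty_c = penalty_c, min_samples = min_samples,
                 edge_trim = edge_trim,
                 speed_threshold = speed_threshold, n_bins = n_bins,
                 mass_fractions = mass_fractions, conf_level = conf_level),
            class = "run_config")
}

config_digest <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                              auto_unbox = TRUE, digits = NA, force = TRUE), tmp)
  unname(tools::md5sum(tmp))
}

pkg_version <- function() {
  tryCatch(as.character(utils::packageVersion("okndrive")),
           error = function(e) "dev")
}

#' Simulate a cohort to disk
#'
#' Writes one CSV + ground-truth JSON per trial plus a `manifest.json`
#' listing every file with its MD5 checksum, the configuration digest and
#' the package version.
#'
#' @param config a [run_config()].
#' @param out_dir output directory (created if needed).
#' @return the manifest, invisibly.
#' @export
run_simulate <- function(config, out_dir) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  trials <- simulate_cohort(config$sim)
  files <- character(length(trials))
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fn <- sprintf("trial_%s_%02d_%s.csv", tr$meta$subject, tr$meta$trial,
                  tr$meta$condition)
    write_trial_csv(tr, file.path(out_dir, fn))
    files[i] <- fn
  }
  manifest <- list(
    config_md5 = config_digest(config), version = pkg_version(),
    master_seed = config$sim$master_seed,
    n_trials = length(trials),
    trials = data.frame(
      file = files,
      subject = vapply(trials, function(x) x$meta$subject, character(1)),
      trial = vapply(trials, function(x) x$meta$trial, integer(1)),
      condition = vapply(trials, function(x) x$meta$condition, character(1)),
      md5 = unname(tools::md5sum(file.path(out_dir, files)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

#' Detect segments for a cohort in memory
#'
#' Aligns every trial to the first trial of the cohort (the prototype) and
#' runs [detect_segments()] on each.
#'
#' @param trials list of `trial_record`s.
#' @param config a [run_config()].
#' @return combined segment table.
#' @export
detect_cohort <- function(trials, config = run_config()) {
  if (!length(trials)) return(empty_segments())
  proto <- trials[[1]]
  out <- lapply(trials, function(tr) {
    al <- align_trial(tr, prototype = proto,
                      quality_threshold = config$quality_threshold)
    detect_segments(al, penalty_c = config$penalty_c,
                    speed_threshold = config$speed_threshold,
                    min_samples = config$min_samples,
                    edge_trim = config$edge_trim)
  })
  do.call(rbind, out)
}

#' Detect segments for trial files on disk
#'
#' Reads every `trial_*.csv` in `in_dir`, preprocesses and partitions it,
#' and writes a combined `segments.tsv`. Malformed files are reported and
#' skipped; the run continues.
#'
#' @param config a [run_config()].
#' @param in_dir directory of trial CSVs from [run_simulate()].
#' @param out_file output TSV path (default `segments.tsv` in `in_dir`).
#' @return list with the segment table and a per-file status data.frame.
#' @export
run_detect <- function(config, in_dir, out_file = file.path(in_dir, "segments.tsv")) {
  files <- sort(list.files(in_dir, pattern = "^trial_.*\\.csv$",
                           full.names = TRUE))
  if (!length(files)) stop("no trial files in ", in_dir)
  trials <- list()
  status <- data.frame(file = basename(files), ok = TRUE,
                       message = "", stringsAsFactors = FALSE)
  for (i in seq_along(files)) {
    tr <- tryCatch(read_trial_csv(files[i]), error = function(e) e)
    if (inherits(tr, "error")) {
      status$ok[i] <- FALSE
      status$message[i] <- conditionMessage(tr)
      message("skipping ", basename(files[i]), ": ", conditionMessage(tr))
      next
    }
    trials[[length(trials) + 1L]] <- tr
  }
  if (!length(trials)) stop("no readable trial files in ", in_dir)
  segments <- detect_cohort(trials, config)
  write_segments_tsv(segments, out_file)
  message(sprintf("detected %d segments (%d slow phases) across %d trials",
                  nrow(segments), sum(segments$class == "slow_phase"),
                  length(trials)))
  invisible(list(segments = segments, status = status))
}

#' Analyze a segment table
#'
#' Produces the full analysis from a segment table: per-segment Delta
#' statistics, group inference with condition contrasts, the slow-phase
#' direction histogram, HDR density levels of the 2-D slow-phase
#' velocities, and per-trial strategy classification. All parameters and
#' sign conventions are echoed into the result.
#'
#' @param segments segment table from [detect_cohort()]/[run_detect()].
#' @param config a [run_config()].
#' @return list (class `okn_report`) with elements `parameters`, `stats`,
#'   `group`, `histogram`, `hdr`, `classification`.
#' @export
analyze_segments <- function(segments, config = run_config()) {
  stats_df <- velocity_statistic(segments)
  if (nrow(stats_df) == 0) {
    return(structure(list(parameters = report_parameters(config),
                          status = "empty: no cornering slow phases"),
                     class = "okn_report"))
  }
  group <- group_inference(stats_df, conf_level = config$conf_level)
  hist <- direction_histogram(segments, n_bins = config$n_bins)
  sp <- segments[segments$class == "slow_phase" &
                   segments$phase == "cornering", , drop = FALSE]
  hdr <- if (nrow(sp) >= 30) {
    hdr_mass_threshold(sp$slope_h, sp$slope_v, mass = config$mass_fractions)
  } else NULL
  cls <- classify_trial_strategy(stats_df)
  structure(list(parameters = report_parameters(config),
                 stats = stats_df, group = group, histogram = hist,
                 hdr = hdr, classification = cls,
                 accuracy = mean(cls$correct)),
            class = "okn_report")
}

report_parameters <- function(config) {
  list(quality_threshold = config$quality_threshold,
       penalty_c = config$penalty_c,
       min_samples = config$min_samples,
       edge_trim = config$edge_trim,
       speed_threshold_dps = config$speed_threshold,
       n_bins = config$n_bins,
       mass_fractions = config$mass_fractions,
       conf_level = config$conf_level,
       conventions = list(
         horizontal = "deg, positive right of heading",
         vertical = "deg, positive below horizon",
         direction_zero = "vehicle-frame upward, positive clockwise",
         delta = "0.5*|mean yaw| - against-bend horizontal SP velocity; tangent-point fixation positive"),
       config_md5 = config_digest(config),
       version = pkg_version())
}

#' @export
print.okn_report <- function(x, ...) {
  cat("<okn_report>\n")
  if (!is.null(x$status)) {
    cat("  ", x$status, "\n")
    return(invisible(x))
  }
  print(x$group)
  cat(sprintf("  trial strategy classification accuracy: %.1f%%\n",
              100 * x$accuracy))
  invisible(x)
}

#' Analyze a segments TSV on disk
#'
#' Runs [analyze_segments()] and writes `report.json` plus TSV tables
#' (`per_subject.tsv`, `histogram.tsv`, `delta_stats.tsv`) to `out_dir`.
#'
#' @param config a [run_config()].
#' @param segments_file path to a segments TSV.
#' @param out_dir output directory.
#' @return the `okn_report`, invisibly.
#' @export
run_analyze <- function(config, segments_file, out_dir) {
  segments <- read_segments_tsv(segments_file)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  rep <- analyze_segments(segments, config)
  json <- list(parameters = rep$parameters)
  if (is.null(rep$status)) {
    json$groups <- rep$group$groups
    json$per_subject <- rep$group$per_subject
    json$paired_normal_tp <- rep$group$paired_normal_tp
    json$independent_normal_control <- rep$group$independent_normal_control
    json$pooled_ci <- rep$group$pooled_ci
    json$hdr <- rep$hdr
    json$classification_accuracy <- rep$accuracy
    utils::write.table(rep$group$per_subject,
                       file.path(out_dir, "per_subject.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rep$histogram, file.path(out_dir, "histogram.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(rep$stats, file.path(out_dir, "delta_stats.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  } else {
    json$status <- rep$status
  }
  jsonlite::write_json(json, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(rep)
}

#' Run the full pipeline
#'
#' simulate -> detect -> analyze, equivalent to chaining [run_simulate()],
#' [run_detect()] and [run_analyze()] on the same directories.
#'
#' @param config a [run_config()].
#' @param out_dir working directory for all outputs.
#' @return the `okn_report`, invisibly.
#' @export
run_all <- function(config, out_dir) {
  run_simulate(config, file.path(out_dir, "trials"))
  det <- run_detect(config, file.path(out_dir, "trials"),
                    file.path(out_dir, "segments.tsv"))
  run_analyze(config, file.path(out_dir, "segments.tsv"),
              file.path(out_dir, "analysis"))
}

#' Plot slow-phase velocities
#'
#' Simple summary plot of the 2-D slow-phase velocity distribution by
#' condition with the waypoint-tracking prediction (-1/2 mean yaw rate)
#' marked. Requires ggplot2.
#'
#' @param segments segment table.
#' @return a ggplot object.
#' @export
plot_sp_velocities <- function(segments) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("plot_sp_velocities requires ggplot2")
  }
  sp <- segments[segments$class == "slow_phase" &
                   segments$phase == "cornering", , drop = FALSE]
  pred <- -mean(abs(sp$yaw_mean)) / 2
  ggplot2::ggplot(sp, ggplot2::aes(x = slope_h, y = slope_v,
                                   colour = condition)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = pred, linetype = "dashed") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey50") +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "horizontal SP velocity (deg/s)",
                  y = "vertical SP velocity (deg/s, downward positive)")
}
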
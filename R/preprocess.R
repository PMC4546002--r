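# Quality filtering, multirate resampling, trial-to-prototype alignment by
# position, and bend phase segmentation.

#' Flag low-quality gaze samples
#'
#' Marks gaze samples whose tracker quality falls strictly below
#' `threshold` as excluded (they are flagged, not deleted). Samples with
#' quality exactly equal to the threshold are retained.
#'
#' @param trial a `trial_record`.
#' @param threshold quality criterion in \[0, 1\] (default 0.2).
#' @return the trial with logical column `excluded` and character column
#'   `excl_reason` added to `$gaze`.
#' @export
quality_filter <- function(trial, threshold = 0.2) {
  stopifnot(inherits(trial, "trial_record"))
  q <- trial$gaze$quality
  excl <- q < threshold
  trial$gaze$excluded <- excl
  trial$gaze$excl_reason <- ifelse(excl, "low_quality", "")
  trial
}

#' Resample a time series to new timestamps
#'
#' Upsampling uses linear interpolation at the target timestamps;
#' downsampling selects the nearest preceding source sample (zero-order
#' hold). Endpoints are clamped to the first/last source value.
#'
#' @param t_src source timestamps (s), strictly increasing.
#' @param y_src source values.
#' @param t_target target timestamps (s).
#' @param method `"linear"` or `"nearest_preceding"`; the default picks
#'   linear when the target rate exceeds the source rate and
#'   nearest-preceding otherwise.
#' @return numeric vector of values at `t_target`.
#' @export
resample <- function(t_src, y_src, t_target,
                     method = c("auto", "linear", "nearest_preceding")) {
  method <- match.arg(method)
  if (length(t_src) == 0) stop("empty series")
  if (length(t_src) == 1) return(rep(y_src, length(t_target)))
  if (is.unsorted(t_src, strictly = TRUE)) stop("source series must be time-ordered")
  if (method == "auto") {
    src_rate <- 1 / stats::median(diff(t_src))
    tgt_rate <- 1 / stats::median(diff(t_target))
    method <- if (tgt_rate > src_rate) "linear" else "nearest_preceding"
  }
  f <- switch(method, linear = stats::approx(t_src, y_src, t_target,
                                             method = "linear", rule = 2),
              nearest_preceding = stats::approx(t_src, y_src, t_target,
                                                method = "constant", f = 0,
                                                rule = 2))
  f$y
}

#' Align trial positions to a prototype trace
#'
#' Assigns each trial position the along-route distance of its nearest
#' prototype point (Euclidean nearest neighbour against the prototype's
#' cumulative arc length), then repairs the distance series to be
#' non-decreasing (running maximum). Points farther than `max_dist` from
#' any prototype point are flagged as alignment failures.
#'
#' @param xy matrix/data.frame of trial positions (columns x, y in m).
#' @param proto_xy matrix/data.frame of prototype positions (m), in route
#'   order.
#' @param max_dist nearest-neighbour distance (m) beyond which alignment is
#'   considered failed for that sample.
#' @return data.frame with columns `dist_m` (non-decreasing) and
#'   `align_failed` (logical).
#' @export
align_to_prototype <- function(xy, proto_xy, max_dist = 25) {
  xy <- as.matrix(xy)[, 1:2, drop = FALSE]
  proto <- as.matrix(proto_xy)[, 1:2, drop = FALSE]
  if (nrow(proto) < 2) stop("prototype must have at least 2 positions")
  proto_dist <- c(0, cumsum(sqrt(diff(proto[, 1])^2 + diff(proto[, 2])^2)))
  # brute-force nearest neighbour; problem sizes here are ~1e3 x 1e3
  d2 <- outer(xy[, 1], proto[, 1], "-")^2 + outer(xy[, 2], proto[, 2], "-")^2
  nn <- max.col(-d2, ties.method = "first")
  nn_d <- sqrt(d2[cbind(seq_len(nrow(xy)), nn)])
  data.frame(dist_m = cummax(proto_dist[nn]), align_failed = nn_d > max_dist)
}

#' Label bend phases along the route
#'
#' Maps along-route distances to analysis phases. With cornering onset at
#' `onset_dist` and the cornering arc ending `arc_length` metres later:
#' `entry` is the half-open interval `[onset - entry_length, onset)`,
#' `cornering` is `[onset, onset + arc_length - exit_cutoff]` (closed at
#' the end), `approach` precedes the entry from the distance at which the
#' tangent point first lies within `fov_half_angle` of the heading, and
#' everything else is `excluded`.
#'
#' @param dist_m numeric vector of along-route distances (m).
#' @param bend a [bend_geometry()].
#' @param onset_dist along-route distance of cornering onset (m).
#' @param path_radius driven radius (m), used for the arc length.
#' @param approach_start distance at which the approach begins (m); by
#'   default the tangent point of this parametric bend is visible from the
#'   start of the record, so the approach starts at 0.
#' @param fov_half_angle field-of-view half angle (deg) defining tangent
#'   point visibility for the approach proxy.
#' @return character vector of phase labels (`approach`, `entry`,
#'   `cornering`, `excluded`).
#' @export
segment_bend <- function(dist_m, bend, onset_dist,
                         path_radius = mid_lane_radius(bend),
                         approach_start = NULL, fov_half_angle = 90) {
  arc_len <- cornering_arc_length(bend, path_radius)
  if (arc_len <= bend$exit_cutoff) {
    stop("configuration error: cornering length must exceed exit_cutoff")
  }
  entry_start <- onset_dist - bend$entry_length
  corner_end <- onset_dist + arc_len - bend$exit_cutoff
  if (is.null(approach_start)) {
    # proxy for "visual onset of the tangent point": distance from which the
    # geometric TP direction exists and lies within the field of view. On
    # the straight approach of this parametric route that holds throughout,
    # so the approach begins at the start of the record.
    approach_start <- 0
  }
  phase <- rep("excluded", length(dist_m))
  phase[dist_m >= approach_start & dist_m < entry_start] <- "approach"
  phase[dist_m >= entry_start & dist_m < onset_dist] <- "entry"
  phase[dist_m >= onset_dist & dist_m <= corner_end] <- "cornering"
  phase
}

#' Align a trial and label its phases
#'
#' Full preprocessing of one trial: quality filtering, resampling of the
#' CAN channel to the 60 Hz gaze timestamps (nearest preceding sample) and
#' of the GPS positions (linear interpolation), alignment of the positions
#' to a prototype trial, and bend phase segmentation.
#'
#' @param trial a `trial_record`.
#' @param prototype a `trial_record` serving as the route reference;
#'   defaults to the trial itself (self-alignment, distances become the
#'   trial's own cumulative arc length).
#' @param quality_threshold tracker quality criterion (default 0.2).
#' @param onset_dist along-route distance of cornering onset; taken from
#'   the prototype's metadata when available.
#' @return the trial with `$gaze` gaining columns `speed_mps`, `yaw_dps`,
#'   `x_m`, `y_m`, `dist_m`, `phase`, `excluded`, `excl_reason` (class
#'   `aligned_trial` prepended).
#' @export
align_trial <- function(trial, prototype = trial, quality_threshold = 0.2,
                        onset_dist = NULL) {
  stopifnot(inherits(trial, "trial_record"))
  trial <- quality_filter(trial, quality_threshold)
  g <- trial$gaze
  g$speed_mps <- resample(trial$can$t, trial$can$speed_mps, g$t, "nearest_preceding")
  g$yaw_dps <- resample(trial$can$t, trial$can$yaw_dps, g$t, "nearest_preceding")
  g$x_m <- resample(trial$gps$t, trial$gps$x_m, g$t, "linear")
  g$y_m <- resample(trial$gps$t, trial$gps$y_m, g$t, "linear")
  proto_xy <- cbind(resample(prototype$gps$t, prototype$gps$x_m,
                             prototype$gaze$t, "linear"),
                    resample(prototype$gps$t, prototype$gps$y_m,
                             prototype$gaze$t, "linear"))
  al <- align_to_prototype(cbind(g$x_m, g$y_m), proto_xy)
  g$dist_m <- al$dist_m
  g$excluded <- g$excluded | al$align_failed
  g$excl_reason[al$align_failed & g$excl_reason == ""] <- "alignment_failure"
  onset_dist <- onset_dist %||% prototype$meta$s_onset %||% trial$meta$s_onset
  if (is.null(onset_dist)) {
    stop("onset_dist must be supplied when trial metadata lacks s_onset")
  }
  bend <- trial$meta$bend
  g$phase <- segment_bend(g$dist_m, bend, onset_dist,
                          path_radius = trial$meta$path_radius %||%
                            mid_lane_radius(bend))
  # excluded-by-metadata trials (traffic, weather, ...) propagate a reason
  if (length(trial$meta$flags) && any(trial$meta$flags %in%
        c("traffic", "rain_wipers", "sunlight", "calibration"))) {
    g$excluded <- TRUE
    g$excl_reason <- trial$meta$flags[1]
  }
  trial$gaze <- g
  class(trial) <- c("aligned_trial", class(trial))
  trial
}
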
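# Seeded simulator of multirate driving-gaze sensor records.
#
# A simulated trial emulates the sensor suite of an instrumented car: remote
# eye tracker at 60 Hz (horizontal/vertical gaze angle plus a 0-1 quality
# signal), CAN-bus speed and yaw rate at 100 Hz, and GPS position at 1 Hz.
# The route is a straight approach + entry leading into a constant-radius
# bend. Three gaze strategies are modelled:
#
#   * "waypoint"  - optokinetic nystagmus from tracking successive
#                   world-fixed points on the future path: slow phases of
#                   200-400 ms during which the line of sight to the fixated
#                   point rotates at -1/2 yaw rate, separated by small
#                   resetting saccades to a new waypoint `preview_time`
#                   seconds ahead.
#   * "tp"        - steady fixation of the tangent point, whose visual
#                   direction is constant during constant-radius cornering.
#   * "tp_okr"    - tangent-point fixation contaminated by an unsuppressed
#                   optokinetic reflex: gaze drifts with a gain `okr_gain`
#                   along the local optic flow and is reset to the tangent
#                   point by corrective saccades.
#
# Every trial carries a ground-truth event log so downstream detection and
# statistics are testable without any external data.

GAZE_HZ <- 60
CAN_HZ <- 100
GPS_HZ <- 1

#' Gaze-strategy and sensor-noise parameters
#'
#' @param strategy one of `"waypoint"`, `"tp"`, `"tp_okr"`.
#' @param preview_time look-ahead of the next waypoint along the future
#'   path (s); waypoint strategy only.
#' @param sp_duration_range range of slow-phase durations (s); optokinetic
#'   slow phases in curve driving typically last 0.2-0.4 s.
#' @param saccade_peak_speed nominal peak saccade speed (deg/s) used to set
#'   the saccade ramp duration (clamped to 2-4 samples at 60 Hz).
#' @param noise_sd white tracker noise, per axis (deg).
#' @param vibration_ar1 AR(1) coefficient of the camera-vibration wander.
#' @param vibration_sd AR(1) innovation sd (deg).
#' @param dropout_prob per-sample probability that tracking quality drops
#'   below the exclusion threshold.
#' @param okr_gain reflex gain in \[0, 1\] (`tp_okr` only): fraction of the
#'   local optic-flow rate that drags gaze off the tangent point.
#' @param radius_jitter_sd innovation sd (m) of a zero-mean AR(1) steering
#'   error on the driven radius, perturbing the tangent-point direction in
#'   the `tp` strategies; 0 disables it.
#' @param radius_jitter_ar1 AR(1) coefficient of the steering error.
#' @param eye_height eye height above the ground plane (m).
#' @return object of class `strategy_params`.
#' @export
strategy_params <- function(strategy = c("waypoint", "tp", "tp_okr"),
                            preview_time = 2,
                            sp_duration_range = c(0.2, 0.4),
                            saccade_peak_speed = 300,
                            noise_sd = 0.5,
                            vibration_ar1 = 0.95,
                            vibration_sd = 0.1,
                            dropout_prob = 0.02,
                            okr_gain = 0.5,
                            radius_jitter_sd = 0,
                            radius_jitter_ar1 = 0.98,
                            eye_height = 1.2) {
  strategy <- match.arg(strategy)
  stopifnot(length(sp_duration_range) == 2,
            sp_duration_range[1] > 0,
            sp_duration_range[1] < sp_duration_range[2])
  if (dropout_prob < 0 || dropout_prob > 1) stop("dropout_prob must be in [0,1]")
  if (okr_gain < 0 || okr_gain > 1) stop("okr_gain must be in [0,1]")
  if (noise_sd < 0 || vibration_sd < 0) stop("noise sds must be >= 0")
  if (preview_time <= 0) stop("preview_time must be > 0")
  structure(as.list(environment()), class = "strategy_params")
}

# Vehicle state along the full route (straight approach+entry, then arc),
# vectorised over along-route distance s. s = s_onset at cornering onset.
route_states <- function(bend, path_radius, speed, s, s_onset) {
  n <- length(s)
  onset <- path_point(bend, path_radius, 0)
  st <- data.frame(t = s / speed, x = numeric(n), y = numeric(n),
                   heading = 0, speed = speed, yaw_rate = 0,
                   heading_rate = 0, path_radius = Inf, arc_position = s - s_onset)
  pre <- s < s_onset
  st$x[pre] <- onset[1] + (s[pre] - s_onset)
  st$y[pre] <- onset[2]
  if (any(!pre)) {
    arc <- vehicle_state_at(bend, path_radius, speed,
                            t = (s[!pre] - s_onset) / speed)
    st$x[!pre] <- arc$x
    st$y[!pre] <- arc$y
    st$heading[!pre] <- arc$heading
    st$yaw_rate[!pre] <- arc$yaw_rate
    st$heading_rate[!pre] <- arc$heading_rate
    st$path_radius[!pre] <- path_radius
  }
  st
}

# World point on the future path at along-route distance s (s may exceed the
# cornering arc end: the path circle continues, as the road does).
route_path_point <- function(bend, path_radius, s, s_onset) {
  onset <- path_point(bend, path_radius, 0)
  out <- cbind(x = onset[1] + (s - s_onset), y = rep(onset[2], length(s)))
  on_arc <- s >= s_onset
  if (any(on_arc)) out[on_arc, ] <- path_point(bend, path_radius, s[on_arc] - s_onset)
  out
}

#' Simulate one noiseless trial
#'
#' Generates a clean (noise-free) multirate sensor record of one traversal
#' of `bend` at constant `speed`, under the gaze strategy in `params`, with
#' an exact ground-truth log of every slow phase and saccade. Sensor noise
#' is added separately by [add_sensor_noise()].
#'
#' @param bend a [bend_geometry()].
#' @param params a [strategy_params()].
#' @param speed vehicle speed (m/s).
#' @param seed integer seed (slow-phase durations and saccade lengths are
#'   random).
#' @param path_radius driven radius (m); defaults to mid-lane.
#' @param approach_length straight distance before the entry phase (m).
#' @param subject,trial,condition labels stored in the trial metadata.
#' @return object of class `trial_record`: a list with data.frames `gaze`
#'   (60 Hz: `t`, `gh_deg`, `gv_deg`, `quality`), `can` (100 Hz: `t`,
#'   `speed_mps`, `yaw_dps` — allocentric heading rate, CCW positive),
#'   `gps` (1 Hz: `t`, `x_m`, `y_m`), `ground_truth` (`t_start`, `t_end`,
#'   `type`, `target_id`) and `meta`.
#' @examples
#' tr <- simulate_trial(bend_geometry(), strategy_params("tp"),
#'                      speed = 42 / 3.6, seed = 1)
#' head(tr$gaze)
#' @export
simulate_trial <- function(bend, params, speed, seed,
                           path_radius = mid_lane_radius(bend),
                           approach_length = 30,
                           subject = "s1", trial = 1L,
                           condition = c("normal", "tp", "control")) {
  condition <- match.arg(condition)
  stopifnot(inherits(bend, "bend_geometry"), inherits(params, "strategy_params"))
  if (!(speed > 0)) stop("speed must be > 0")
  s_onset <- approach_length + bend$entry_length
  L <- s_onset + cornering_arc_length(bend, path_radius)
  flags <- character()

  n60 <- floor(L / speed * GAZE_HZ) + 1L
  t60 <- (seq_len(n60) - 1L) / GAZE_HZ
  s60 <- t60 * speed
  st <- route_states(bend, path_radius, speed, s60, s_onset)

  gh <- numeric(n60)
  gv <- numeric(n60)
  events <- list()

  if (params$strategy == "waypoint") {
    res <- with_seed(seed, simulate_waypoint_gaze(
      bend, params, speed, st, s60, s_onset, L))
    gh <- res$gh; gv <- res$gv; events <- res$events; flags <- res$flags
  } else {
    # tangent-point strategies; optional AR(1) steering error on the radius
    d <- rep(path_radius, n60)
    res <- with_seed(seed, {
      if (params$radius_jitter_sd > 0) {
        jit <- as.numeric(stats::filter(
          stats::rnorm(n60, 0, params$radius_jitter_sd),
          params$radius_jitter_ar1, method = "recursive"))
        d <- pmax(d + jit, bend$inner_edge_radius + 0.5)
      }
      tp_h <- tp_direction_at_distance(st, bend, d, params$eye_height)
      if (params$strategy == "tp") {
        list(gh = tp_h$horizontal, gv = tp_h$vertical,
             events = list(data.frame(t_start = t60[1], t_end = t60[n60],
                                      type = "slow_phase", target_id = "tp")),
             flags = character())
      } else {
        simulate_tp_okr_gaze(bend, params, speed, st, s60, s_onset, tp_h, t60)
      }
    })
    gh <- res$gh; gv <- res$gv; events <- res$events
    flags <- c(flags, res$flags)
  }

  # CAN 100 Hz and GPS 1 Hz channels from the same kinematics
  n100 <- floor(L / speed * CAN_HZ) + 1L
  t100 <- (seq_len(n100) - 1L) / CAN_HZ
  st100 <- route_states(bend, path_radius, speed, t100 * speed, s_onset)
  t1 <- seq(0, floor(L / speed), by = 1 / GPS_HZ)
  st1 <- route_states(bend, path_radius, speed, t1 * speed, s_onset)

  structure(list(
    gaze = data.frame(t = t60, gh_deg = gh, gv_deg = gv, quality = 1),
    can = data.frame(t = t100, speed_mps = st100$speed,
                     yaw_dps = st100$heading_rate),
    gps = data.frame(t = t1, x_m = st1$x, y_m = st1$y),
    ground_truth = do.call(rbind, events),
    meta = list(subject = subject, trial = as.integer(trial),
                condition = condition, strategy = params$strategy,
                bend = bend, path_radius = path_radius, speed = speed,
                approach_length = approach_length,
                s_onset = s_onset, route_length = L,
                eye_height = params$eye_height, seed = seed,
                flags = flags)),
    class = "trial_record")
}

# TP direction allowing a per-sample perturbed distance-from-center d
# (steering-error jitter, applied on the arc only by radially displacing
# the vehicle position; heading is left untouched since gaze is recorded
# relative to the actual heading).
tp_direction_at_distance <- function(st, bend, d, eye_height) {
  true_d <- sqrt((st$x - bend$center[1])^2 + (st$y - bend$center[2])^2)
  on_arc <- is.finite(st$path_radius)
  scale <- ifelse(on_arc & true_d > 0, d / true_d, 1)
  st2 <- st
  st2$x <- bend$center[1] + (st$x - bend$center[1]) * scale
  st2$y <- bend$center[2] + (st$y - bend$center[2]) * scale
  tangent_point_direction(st2, bend, eye_height = eye_height)
}

simulate_waypoint_gaze <- function(bend, params, speed, st, s60, s_onset, L) {
  n <- nrow(st)
  t60 <- st$t
  gh <- numeric(n); gv <- numeric(n)
  events <- list()
  flags <- character()
  target_count <- 0L

  # path radius for target placement: take it from the arc part of st
  pr <- st$path_radius[is.finite(st$path_radius)][1]
  new_target <- function(s_now) {
    target_count <<- target_count + 1L
    s_t <- s_now + params$preview_time * speed
    if (s_t > L) flags <<- unique(c(flags, "truncated_preview"))
    list(id = sprintf("wp%03d", target_count),
         pos = route_path_point(bend, pr, s_t, s_onset))
  }

  tgt <- new_target(s60[1])
  i <- 1L
  while (i <= n) {
    dur <- stats::runif(1, params$sp_duration_range[1], params$sp_duration_range[2])
    i_end <- min(n, i + as.integer(round(dur * GAZE_HZ)))
    idx <- i:i_end
    dir <- egocentric_direction(st[idx, , drop = FALSE],
                                matrix(tgt$pos, nrow = length(idx), ncol = 2,
                                       byrow = TRUE))
    gh[idx] <- dir$horizontal
    gv[idx] <- vertical_direction(st[idx, , drop = FALSE],
                                  matrix(tgt$pos, nrow = length(idx), ncol = 2,
                                         byrow = TRUE), params$eye_height)
    events[[length(events) + 1L]] <- data.frame(
      t_start = t60[i], t_end = t60[i_end], type = "slow_phase",
      target_id = tgt$id)
    if (i_end >= n) break
    # resetting saccade to the next waypoint
    nxt <- new_target(s60[min(n, i_end + 1L)])
    amp_guess <- abs(egocentric_direction(
      st[i_end, , drop = FALSE], nxt$pos)$horizontal - gh[i_end])
    ns <- max(2L, min(4L, as.integer(ceiling(amp_guess / params$saccade_peak_speed * GAZE_HZ))))
    j_end <- min(n, i_end + ns)
    j_next <- min(n, j_end + 1L)
    goal <- egocentric_direction(st[j_next, , drop = FALSE], nxt$pos)
    goal_v <- vertical_direction(st[j_next, , drop = FALSE], nxt$pos,
                                 params$eye_height)
    jdx <- (i_end + 1L):j_end
    frac <- seq_along(jdx) / length(jdx)
    gh[jdx] <- gh[i_end] + frac * (goal$horizontal - gh[i_end])
    gv[jdx] <- gv[i_end] + frac * (goal_v - gv[i_end])
    events[[length(events) + 1L]] <- data.frame(
      t_start = t60[i_end + 1L], t_end = t60[j_end], type = "saccade",
      target_id = nxt$id)
    tgt <- nxt
    i <- j_end + 1L
  }
  list(gh = gh, gv = gv, events = events, flags = flags)
}

simulate_tp_okr_gaze <- function(bend, params, speed, st, s60, s_onset, tp_h, t60) {
  n <- nrow(st)
  gh <- tp_h$horizontal; gv <- tp_h$vertical
  # local optic-flow rate: horizontal rate of a path point ~1.5 s ahead
  pr <- st$path_radius[is.finite(st$path_radius)][1]
  flow_pt <- route_path_point(bend, pr, s60 + 1.5 * speed, s_onset)
  flow_h <- gaze_angle_rate(st, flow_pt)
  events <- list()
  i <- 1L
  cycle <- 0L
  dt <- 1 / GAZE_HZ
  while (i <= n) {
    cycle <- cycle + 1L
    dur <- stats::runif(1, params$sp_duration_range[1], params$sp_duration_range[2])
    i_end <- min(n, i + as.integer(round(dur * GAZE_HZ)))
    idx <- i:i_end
    drift <- cumsum(params$okr_gain * flow_h[idx] * dt) -
      params$okr_gain * flow_h[idx[1]] * dt
    gh[idx] <- gh[idx] + drift
    gv[idx] <- gv[idx] + cumsum(rep(params$okr_gain * 0.3 * dt, length(idx)))
    events[[length(events) + 1L]] <- data.frame(
      t_start = t60[i], t_end = t60[i_end], type = "slow_phase",
      target_id = sprintf("tp_okr%03d", cycle))
    if (i_end >= n) break
    ns <- 2L
    j_end <- min(n, i_end + ns)
    jdx <- (i_end + 1L):j_end
    frac <- seq_along(jdx) / length(jdx)
    gh[jdx] <- gh[i_end] + frac * (tp_h$horizontal[j_end] - gh[i_end])
    gv[jdx] <- gv[i_end] + frac * (tp_h$vertical[j_end] - gv[i_end])
    events[[length(events) + 1L]] <- data.frame(
      t_start = t60[i_end + 1L], t_end = t60[j_end], type = "saccade",
      target_id = "tp")
    i <- j_end + 1L
  }
  list(gh = gh, gv = gv, events = events, flags = character())
}

#' Add tracker noise, camera vibration and quality dropouts
#'
#' Adds white Gaussian noise (`noise_sd`) and AR(1) vibration wander to both
#' gaze axes, Gaussian position noise to the GPS channel, and draws quality
#' dropouts: each 60 Hz sample independently falls below the 0.2 quality
#' criterion with probability `dropout_prob`. The ground-truth event log is
#' unchanged.
#'
#' @param trial a `trial_record` from [simulate_trial()].
#' @param params a [strategy_params()].
#' @param seed integer seed.
#' @param gps_noise_sd GPS position noise sd (m).
#' @return the noisy `trial_record`.
#' @export
add_sensor_noise <- function(trial, params, seed, gps_noise_sd = 0.5) {
  stopifnot(inherits(trial, "trial_record"))
  n <- nrow(trial$gaze)
  with_seed(seed, {
    for (col in c("gh_deg", "gv_deg")) {
      noise <- if (params$noise_sd > 0) stats::rnorm(n, 0, params$noise_sd) else 0
      vib <- if (params$vibration_sd > 0) {
        as.numeric(stats::filter(stats::rnorm(n, 0, params$vibration_sd),
                                 params$vibration_ar1, method = "recursive"))
      } else 0
      trial$gaze[[col]] <- trial$gaze[[col]] + noise + vib
    }
    qual <- stats::runif(n, 0.6, 1)
    if (params$dropout_prob > 0) {
      drop <- stats::runif(n) < params$dropout_prob
      qual[drop] <- stats::runif(sum(drop), 0, 0.15)
    }
    trial$gaze$quality <- qual
    if (gps_noise_sd > 0) {
      m <- nrow(trial$gps)
      trial$gps$x_m <- trial$gps$x_m + stats::rnorm(m, 0, gps_noise_sd)
      trial$gps$y_m <- trial$gps$y_m + stats::rnorm(m, 0, gps_noise_sd)
    }
  })
  trial
}

#' Cohort simulation configuration
#'
#' Describes a cohort of virtual drivers reproducing the experiment's block
#' design: each subject drives `2 * trials_per_condition` laps split into
#' four alternating blocks, "normal" (free gaze, modelled as future-path
#' waypoint tracking) and "tp" (instructed tangent-point fixation), i.e.
#' normal-tp-normal-tp. Optionally an independent control group of
#' uninstructed drivers (waypoint strategy throughout) is added.
#'
#' @param n_subjects number of subjects in the two-condition experiment.
#' @param trials_per_condition trials per condition per subject (split into
#'   two blocks).
#' @param bends list of [bend_geometry()] cycled over trials.
#' @param speed_mean,speed_sd between-subject mean speed and sd (m/s); the
#'   defaults correspond to 42 km/h with an sd of 3.95 km/h.
#' @param speed_trial_sd within-subject trial-to-trial speed sd (m/s).
#' @param preview_mean,preview_sd between-subject waypoint preview time
#'   distribution (s).
#' @param normal_params,tp_params,control_params [strategy_params()]
#'   templates for each condition.
#' @param n_control_subjects size of the independent control group (0 for
#'   none).
#' @param master_seed master seed; every stochastic stage derives from it.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 7, trials_per_condition = 8,
                       bends = list(bend_geometry()),
                       speed_mean = 42 / 3.6, speed_sd = 3.95 / 3.6,
                       speed_trial_sd = 0.3,
                       preview_mean = 2, preview_sd = 0.3,
                       normal_params = strategy_params("waypoint"),
                       tp_params = strategy_params("tp"),
                       control_params = strategy_params("waypoint"),
                       n_control_subjects = 0,
                       master_seed = 2015) {
  stopifnot(n_subjects >= 1, trials_per_condition >= 1,
            speed_mean > 0, length(bends) >= 1)
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate a cohort of trials
#'
#' Runs [simulate_trial()] + [add_sensor_noise()] for every subject and
#' trial of `config`, with per-subject jittered speeds and preview times and
#' the four-block normal-tp-normal-tp ordering. Fully deterministic under
#' `config$master_seed`.
#'
#' @param config a [sim_config()].
#' @return list of `trial_record`s (class `trial_cohort`).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  k <- config$trials_per_condition
  b1 <- ceiling(k / 2); b2 <- k - b1
  cond_seq <- c(rep("normal", b1), rep("tp", b1),
                rep("normal", b2), rep("tp", b2))
  n_main_trials <- config$n_subjects * length(cond_seq)
  n_ctrl_trials <- config$n_control_subjects * 2 * k
  seeds <- derive_seeds(config$master_seed,
                        2 * (config$n_subjects + config$n_control_subjects) +
                          2 * (n_main_trials + n_ctrl_trials))
  si <- 0L
  next_seed <- function() { si <<- si + 1L; seeds[si] }

  trials <- list()
  make_subject <- function(subject_id, conds, group) {
    sp_speed <- max(5, with_seed(next_seed(),
                                 stats::rnorm(1, config$speed_mean, config$speed_sd)))
    sp_preview <- max(0.8, with_seed(next_seed(),
                                     stats::rnorm(1, config$preview_mean, config$preview_sd)))
    for (j in seq_along(conds)) {
      cond <- conds[j]
      bend <- config$bends[[(j - 1L) %% length(config$bends) + 1L]]
      pars <- switch(cond,
                     normal = config$normal_params,
                     tp = config$tp_params,
                     control = config$control_params)
      if (pars$strategy == "waypoint") pars$preview_time <- sp_preview
      v <- max(5, sp_speed + with_seed(next_seed(),
                                       stats::rnorm(1, 0, config$speed_trial_sd)))
      tr <- simulate_trial(bend, pars, speed = v, seed = next_seed(),
                           subject = subject_id, trial = j, condition = cond)
      tr <- add_sensor_noise(tr, pars, seed = tr$meta$seed + 1L)
      trials[[length(trials) + 1L]] <<- tr
    }
  }
  for (s in seq_len(config$n_subjects)) {
    make_subject(sprintf("s%02d", s), cond_seq, "main")
  }
  for (s in seq_len(config$n_control_subjects)) {
    make_subject(sprintf("c%02d", s), rep("control", 2 * k), "control")
  }
  structure(trials, class = "trial_cohort")
}

#' Write / read a trial as CSV plus a ground-truth sidecar
#'
#' The CSV holds one row per 60 Hz gaze sample with the CAN channel
#' downsampled (nearest preceding sample) and the GPS channel linearly
#' interpolated onto the gaze timestamps; columns `t, gh_deg, gv_deg,
#' quality, speed_mps, yaw_dps, x_m, y_m, subject, trial, condition`. The
#' sidecar JSON (same path with extension `.json`) carries the ground-truth
#' event log and the trial metadata, including the bend geometry.
#'
#' @param trial a `trial_record`.
#' @param path CSV file path.
#' @return `write_trial_csv` returns `path` invisibly; `read_trial_csv`
#'   returns a `trial_record` (with the flattened 60 Hz CAN/GPS channels).
#' @export
write_trial_csv <- function(trial, path) {
  g <- trial$gaze
  df <- data.frame(
    t = g$t, gh_deg = g$gh_deg, gv_deg = g$gv_deg, quality = g$quality,
    speed_mps = resample(trial$can$t, trial$can$speed_mps, g$t, "nearest_preceding"),
    yaw_dps = resample(trial$can$t, trial$can$yaw_dps, g$t, "nearest_preceding"),
    x_m = resample(trial$gps$t, trial$gps$x_m, g$t, "linear"),
    y_m = resample(trial$gps$t, trial$gps$y_m, g$t, "linear"),
    subject = trial$meta$subject, trial = trial$meta$trial,
    condition = trial$meta$condition)
  utils::write.csv(df, path, row.names = FALSE)
  side <- list(
    ground_truth = trial$ground_truth,
    meta = c(trial$meta[setdiff(names(trial$meta), "bend")],
             list(bend = unclass(trial$meta$bend))))
  jsonlite::write_json(side, sub("\\.csv$", ".json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("t", "gh_deg", "gv_deg", "quality", "speed_mps", "yaw_dps",
            "x_m", "y_m", "subject", "trial", "condition")
  if (!all(need %in% names(df)) || nrow(df) == 0) {
    stop("malformed trial CSV: ", path)
  }
  sidecar <- sub("\\.csv$", ".json", path)
  gt <- NULL; meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    gt <- side$ground_truth
    meta <- side$meta
    meta$bend <- bend_geometry(
      center = meta$bend$center,
      inner_edge_radius = meta$bend$inner_edge_radius,
      lane_width = meta$bend$lane_width,
      arc_span = meta$bend$arc_span,
      handedness = meta$bend$handedness,
      entry_length = meta$bend$entry_length,
      exit_cutoff = meta$bend$exit_cutoff,
      id = meta$bend$id %||% "bend")
  }
  meta$subject <- meta$subject %||% df$subject[1]
  meta$trial <- meta$trial %||% df$trial[1]
  meta$condition <- meta$condition %||% df$condition[1]
  structure(list(
    gaze = df[, c("t", "gh_deg", "gv_deg", "quality")],
    can = data.frame(t = df$t, speed_mps = df$speed_mps, yaw_dps = df$yaw_dps),
    gps = data.frame(t = df$t, x_m = df$x_m, y_m = df$y_m),
    ground_truth = gt,
    meta = meta), class = "trial_record")
}

#' @export
print.trial_record <- function(x, ...) {
  cat(sprintf(
    "<trial_record> subject %s trial %s (%s), %d gaze samples, %.1f s, %d ground-truth events\n",
    x$meta$subject, x$meta$trial, x$meta$condition, nrow(x$gaze),
    max(x$gaze$t), if (is.null(x$ground_truth)) 0L else nrow(x$ground_truth)))
  invisible(x)
}
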
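# Optimal piecewise-linear partitioning of 2-D gaze traces into slow eye
# movements and saccades.
#
# The detector exists because differentiating a vibration-contaminated gaze
# signal sample-by-sample buries the slow-phase velocities in noise, while
# low-pass filtering would destroy the saccadic structure. Fixations to
# linearly moving targets (smooth pursuit / OKN slow phases) and saccades
# are both approximately constant-velocity, so the trace is modelled as a
# sequence of linear segments: the partition minimising
#
#   sum over segments of SSE(least-squares line, both axes) +
#   penalty * (number of segments)
#
# is found exactly by dynamic programming over breakpoints. Both axes share
# breakpoints (the eye moves as one).

# Per-axis cumulative statistics so the SSE of a least-squares line over any
# window [i, j] is O(1).
.seg_cum <- function(t, y) {
  list(St = c(0, cumsum(t)), St2 = c(0, cumsum(t * t)),
       Sy = c(0, cumsum(y)), Sy2 = c(0, cumsum(y * y)),
       Sty = c(0, cumsum(t * y)))
}

# Vectorised SSE of segments [i, j] for fixed j and a vector of i.
# Cumulative arrays are zero-prefixed, so sum over [i, j] is S[j+1] - S[i].
.seg_sse <- function(cum, i, j) {
  n <- j - i + 1
  pick <- function(S) S[j + 1] - S[i]
  St <- pick(cum$St); St2 <- pick(cum$St2)
  Sy <- pick(cum$Sy); Sy2 <- pick(cum$Sy2); Sty <- pick(cum$Sty)
  Stt <- St2 - St^2 / n
  Sty_c <- Sty - St * Sy / n
  Syy_c <- Sy2 - Sy^2 / n
  sse <- Syy_c - ifelse(Stt > 0, Sty_c^2 / Stt, 0)
  pmax(sse, 0)  # guard tiny negative round-off
}

#' Optimal piecewise-linear partition of a gaze trace
#'
#' Exact minimiser of the penalised two-axis linear-segment cost by dynamic
#' programming: every partition of the samples into contiguous segments of
#' at least `min_len` samples is considered, and the one minimising the
#' summed squared residuals of per-segment least-squares lines (both axes)
#' plus `penalty` per segment is returned. Deterministic; ties are resolved
#' in favour of the earliest admissible breakpoint.
#'
#' @param t sample times (s).
#' @param gh,gv horizontal and vertical gaze angles (deg).
#' @param penalty segment penalty (squared-degree units), > 0.
#' @param min_len minimum samples per segment (>= 2 so every segment
#'   determines a line).
#' @return object of class `partition_solution`: list with `breaks` (first
#'   sample index of each segment), `ends`, `cost` (total penalised cost),
#'   `sse` (per-segment SSE, both axes), `penalty`, `n`.
#' @export
partition_signal <- function(t, gh, gv, penalty, min_len = 2) {
  n <- length(t)
  stopifnot(length(gh) == n, length(gv) == n)
  if (n < 2) stop("trace must have at least 2 valid samples")
  if (!(penalty > 0)) stop("penalty must be > 0")
  min_len <- max(2L, as.integer(min_len))
  if (n < min_len) stop("trace shorter than min_len")
  t0 <- t - mean(t)  # centre for numerical stability
  ch <- .seg_cum(t0, gh)
  cv <- .seg_cum(t0, gv)
  cost <- rep(Inf, n + 1L)  # cost[k+1] = optimal cost of samples 1..k
  cost[1] <- 0
  prev <- integer(n)
  for (j in seq_len(n)) {
    if (j < min_len) next
    i_cand <- seq_len(j - min_len + 1L)
    i_cand <- i_cand[is.finite(cost[i_cand])]
    if (!length(i_cand)) next
    sse_j <- .seg_sse(ch, i_cand, j) + .seg_sse(cv, i_cand, j)
    tot <- cost[i_cand] + sse_j + penalty
    k <- which.min(tot)
    cost[j + 1L] <- tot[k]
    prev[j] <- i_cand[k]
  }
  if (!is.finite(cost[n + 1L])) stop("no admissible partition")
  # backtrack
  breaks <- integer(0)
  j <- n
  while (j >= 1L) {
    i <- prev[j]
    breaks <- c(i, breaks)
    j <- i - 1L
  }
  ends <- c(breaks[-1] - 1L, n)
  sse <- vapply(seq_along(breaks), function(k) {
    idx <- breaks[k]:ends[k]
    sum(.seg_sse(ch, breaks[k], ends[k]), .seg_sse(cv, breaks[k], ends[k]))
  }, numeric(1))
  structure(list(breaks = breaks, ends = ends, cost = cost[n + 1L],
                 sse = sse, penalty = penalty, n = n),
            class = "partition_solution")
}

#' Merge compatible adjacent segments of a partition
#'
#' Bottom-up refinement pass: adjacent segments are merged (smallest cost
#' first) when the summed squared residual of a joint linear fit exceeds
#' the two separate fits by less than `kappa * sigma^2` (under a common
#' line the increase is a chi-square with 4 degrees of freedom: one slope
#' and one intercept per axis) AND their per-axis slopes differ by less
#' than `slope_gate`. The slope gate keeps steep saccade segments from
#' being folded into neighbouring slow phases; the SSE test re-joins slow
#' phases that the penalised partition split spuriously under correlated
#' tracker noise, which would otherwise be discarded as sub-duration
#' fragments.
#'
#' @param solution a `partition_solution`.
#' @param t,gh,gv the samples the partition was computed on.
#' @param sigma noise scale (deg); defaults to the robust estimate used by
#'   [select_penalty()].
#' @param kappa SSE-increase threshold in units of `sigma^2`. The default
#'   (`NULL`) uses three times the partition penalty (in `sigma^2` units, with
#'   the 0.99 chi-square(4) quantile as a floor), so the pass can undo a
#'   penalised split whose gain barely exceeded the penalty, while an
#'   absorbed saccade jump of amplitude `a` between fragments costs about
#'   `a^2 * n / 4` squared degrees and stays blocked.
#' @param slope_gate maximum per-axis slope difference (deg/s) across a
#'   merged boundary.
#' @param jump_gate maximum per-axis discontinuity (deg) between the two
#'   fitted lines evaluated at the shared boundary. A saccade absorbed
#'   into one of the fragments leaves a step of roughly its amplitude at
#'   the boundary, while a spurious split of one slow phase is continuous
#'   there; the gate blocks the former and admits the latter.
#' @return a refined `partition_solution`.
#' @export
merge_partition <- function(solution, t, gh, gv, sigma = NULL,
                            kappa = NULL, slope_gate = 25, jump_gate = 1) {
  stopifnot(inherits(solution, "partition_solution"))
  if (is.null(sigma)) {
    scale_of <- function(y) stats::median(abs(diff(y))) / (0.6745 * sqrt(2))
    sigma <- max(sqrt((scale_of(gh)^2 + scale_of(gv)^2) / 2), 0.01)
  }
  if (is.null(kappa)) {
    kappa <- max(stats::qchisq(0.99, 4), 3 * solution$penalty / sigma^2)
  }
  t0 <- t - mean(t)
  ch <- .seg_cum(t0, gh)
  cv <- .seg_cum(t0, gv)
  sse_of <- function(i, j) .seg_sse(ch, i, j) + .seg_sse(cv, i, j)
  fit_of <- function(i, j, cum) {
    # slope and mean-anchored intercept of the LS line over [i, j]
    n <- j - i + 1
    St <- cum$St[j + 1] - cum$St[i]
    St2 <- cum$St2[j + 1] - cum$St2[i]
    Sy <- cum$Sy[j + 1] - cum$Sy[i]
    Sty <- cum$Sty[j + 1] - cum$Sty[i]
    Stt <- St2 - St^2 / n
    slope <- if (Stt > 0) (Sty - St * Sy / n) / Stt else 0
    c(slope = slope, t_mean = St / n, y_mean = Sy / n)
  }
  boundary_jump <- function(a, b, cum, tb) {
    fa <- fit_of(a[1], a[2], cum)
    fb <- fit_of(b[1], b[2], cum)
    abs((fa["y_mean"] + fa["slope"] * (tb - fa["t_mean"])) -
          (fb["y_mean"] + fb["slope"] * (tb - fb["t_mean"])))
  }
  breaks <- solution$breaks
  ends <- solution$ends
  repeat {
    k <- length(breaks)
    if (k < 2) break
    inc <- rep(Inf, k - 1)
    for (m in seq_len(k - 1)) {
      fa_h <- fit_of(breaks[m], ends[m], ch)
      fb_h <- fit_of(breaks[m + 1], ends[m + 1], ch)
      fa_v <- fit_of(breaks[m], ends[m], cv)
      fb_v <- fit_of(breaks[m + 1], ends[m + 1], cv)
      if (abs(fa_h["slope"] - fb_h["slope"]) > slope_gate ||
          abs(fa_v["slope"] - fb_v["slope"]) > slope_gate) next
      tb <- (t0[ends[m]] + t0[breaks[m + 1]]) / 2
      jump_h <- boundary_jump(c(breaks[m], ends[m]),
                              c(breaks[m + 1], ends[m + 1]), ch, tb)
      jump_v <- boundary_jump(c(breaks[m], ends[m]),
                              c(breaks[m + 1], ends[m + 1]), cv, tb)
      if (jump_h > jump_gate || jump_v > jump_gate) next
      inc[m] <- sse_of(breaks[m], ends[m + 1]) -
        sse_of(breaks[m], ends[m]) - sse_of(breaks[m + 1], ends[m + 1])
    }
    best <- which.min(inc)
    if (!is.finite(inc[best]) || inc[best] >= kappa * sigma^2) break
    ends[best] <- ends[best + 1]
    breaks <- breaks[-(best + 1)]
    ends <- ends[-(best + 1)]
  }
  sse <- vapply(seq_along(breaks), function(m) sse_of(breaks[m], ends[m]),
                numeric(1))
  structure(list(breaks = breaks, ends = ends,
                 cost = sum(sse) + solution$penalty * length(breaks),
                 sse = sse, penalty = solution$penalty, n = solution$n),
            class = "partition_solution")
}

#' Data-driven segment penalty
#'
#' Sets the partition penalty as `penalty = c * sigma_hat^2 * log(n)`.
#' `sigma_hat^2` is the variance of the residuals a linear segment model
#' must absorb, summed over both axes (as the partition cost is), and
#' estimated robustly as the median across short non-overlapping windows
#' (12 samples, the segment discard length) of the per-window residual
#' variance around a fitted line.
#' Unlike a first-difference estimate, this window-scale estimate also
#' sees slow correlated disturbances (camera-vibration wander) that are
#' nearly invisible in sample-to-sample differences yet deflect a segment
#' from a straight line; the median makes it robust to windows containing
#' saccades. A floor on `sigma_hat` keeps the penalty positive on
#' noiseless traces.
#'
#' @param gh,gv gaze axes (deg).
#' @param c penalty constant (default 1.25; calibrated on synthetic recovery
#'   benchmarks, where larger values merge small resetting saccades into
#'   the surrounding slow phases and smaller ones fragment slow phases).
#' @param sigma_floor lower bound on the noise scale (deg).
#' @param window window length (samples) for the residual-scale estimate.
#' @return penalty (> 0).
#' @export
select_penalty <- function(gh, gv, c = 1.25, sigma_floor = 0.01, window = 12) {
  n <- length(gh)
  # sigma_hat^2 is the TOTAL residual variance summed over both axes, since
  # the partition cost sums both axes' SSE
  if (n < 2 * window) {
    # short trace: fall back to the first-difference scale
    scale_of <- function(y) stats::median(abs(diff(y))) / (0.6745 * sqrt(2))
    sigma2 <- scale_of(gh)^2 + scale_of(gv)^2
    return(c * max(sigma2, sigma_floor^2) * log(max(n, 2)))
  }
  n_win <- n %/% window
  starts <- (seq_len(n_win) - 1L) * window + 1L
  tc <- seq_len(window) - (window + 1) / 2
  stt <- sum(tc^2)
  var_w <- vapply(starts, function(i) {
    idx <- i:(i + window - 1L)
    v <- 0
    for (y in list(gh[idx], gv[idx])) {
      yc <- y - mean(y)
      sse <- sum(yc^2) - sum(tc * yc)^2 / stt
      v <- v + sse
    }
    v / (window - 2)
  }, numeric(1))
  sigma2 <- max(stats::median(var_w), sigma_floor^2)
  c * sigma2 * log(max(n, 2))
}

#' Velocity, amplitude and direction of one segment
#'
#' Least-squares line per axis over the segment samples; the amplitude per
#' axis is the difference of the fitted values at the segment's extremes,
#' speed is the Euclidean norm of the amplitude vector divided by the
#' duration, and direction is the angle of the amplitude vector measured
#' from the vehicle-frame vertical (0 deg = upward in the visual field,
#' positive clockwise, so "left and down" falls on the negative-to--180
#' side).
#'
#' @param t sample times (s), >= 2 samples spanning a positive duration.
#' @param gh,gv gaze axes (deg).
#' @return list with `slope_h`, `slope_v` (deg/s), `amp_h`, `amp_v` (deg),
#'   `duration` (s), `speed` (deg/s), `direction` (deg).
#' @export
segment_velocity <- function(t, gh, gv) {
  if (length(t) < 2) stop("segment must have at least 2 samples")
  dur <- t[length(t)] - t[1]
  if (dur <= 0) stop("segment duration must be positive")
  tc <- t - mean(t)
  stt <- sum(tc^2)
  slope_h <- sum(tc * gh) / stt
  slope_v <- sum(tc * gv) / stt
  amp_h <- slope_h * dur
  amp_v <- slope_v * dur
  speed <- sqrt(amp_h^2 + amp_v^2) / dur
  # 0 deg = upward (gv decreasing since vertical is positive below horizon),
  # positive clockwise (rightward = +90)
  direction <- atan2(amp_h, -amp_v) * RAD2DEG
  list(slope_h = slope_h, slope_v = slope_v, amp_h = amp_h, amp_v = amp_v,
       duration = dur, speed = speed, direction = direction)
}

#' Classify the segments of a partition
#'
#' Turns a [partition_signal()] solution into a table of gaze segments:
#' segments with fewer than `min_samples` samples (200 ms at 60 Hz by
#' default) are discarded, the remainder are saccades when their speed
#' reaches `speed_threshold` and slow phases otherwise.
#'
#' @param solution a `partition_solution`.
#' @param t,gh,gv the samples the partition was computed on.
#' @param yaw optional per-sample yaw rate (deg/s) to average per segment.
#' @param speed_threshold saccade speed threshold (deg/s, default 50).
#' @param min_samples discard threshold (samples, default 12).
#' @param edge_trim boundary samples (per side) excluded from the velocity
#'   fit when the segment is long enough to keep at least 8 interior
#'   samples. Detected breakpoints are localised only to within a few
#'   samples in noisy traces, and mis-assigned boundary samples bias the
#'   fitted slope; the interior fit removes that contamination. Duration
#'   and amplitude still span the full segment (amplitude is the fitted
#'   line evaluated at the segment extremes). Set to 0 to fit all samples.
#' @return data.frame with one row per segment: `t_start`, `t_end`,
#'   `duration`, `n`, `slope_h`, `slope_v`, `amp_h`, `amp_v`, `speed`,
#'   `direction`, `class`, `yaw_mean`.
#' @export
classify_segments <- function(solution, t, gh, gv, yaw = NULL,
                              speed_threshold = 50, min_samples = 12,
                              edge_trim = 3) {
  stopifnot(inherits(solution, "partition_solution"))
  rows <- lapply(seq_along(solution$breaks), function(k) {
    idx <- solution$breaks[k]:solution$ends[k]
    n_seg <- length(idx)
    k_trim <- min(edge_trim, max(0L, (n_seg - 8L) %/% 2L))
    fit_idx <- idx[(1L + k_trim):(n_seg - k_trim)]
    sv <- segment_velocity(t[fit_idx], gh[fit_idx], gv[fit_idx])
    # re-span amplitude/duration over the full segment with the interior fit
    sv$duration <- t[idx[n_seg]] - t[idx[1]]
    sv$amp_h <- sv$slope_h * sv$duration
    sv$amp_v <- sv$slope_v * sv$duration
    sv$speed <- sqrt(sv$amp_h^2 + sv$amp_v^2) / sv$duration
    sv$direction <- atan2(sv$amp_h, -sv$amp_v) * RAD2DEG
    cls <- if (n_seg < min_samples) "discarded"
           else if (sv$speed >= speed_threshold) "saccade"
           else "slow_phase"
    data.frame(t_start = t[idx[1]], t_end = t[idx[length(idx)]],
               duration = sv$duration, n = length(idx),
               slope_h = sv$slope_h, slope_v = sv$slope_v,
               amp_h = sv$amp_h, amp_v = sv$amp_v,
               speed = sv$speed, direction = sv$direction, class = cls,
               yaw_mean = if (is.null(yaw)) NA_real_ else mean(yaw[idx]))
  })
  do.call(rbind, rows)
}

#' Detect gaze segments in an aligned trial
#'
#' Splits the 60 Hz gaze trace at excluded samples into contiguous valid
#' windows (windows shorter than `min_samples` are skipped), chooses a
#' penalty per window with [select_penalty()], partitions each window with
#' [partition_signal()] and classifies the segments. Each segment is
#' labelled with the bend phase at its midpoint sample.
#'
#' @param trial an `aligned_trial` from [align_trial()].
#' @param penalty_c penalty constant passed to [select_penalty()].
#' @param speed_threshold,min_samples,edge_trim see [classify_segments()].
#' @param merge_kappa,merge_slope_gate,merge_jump_gate see
#'   [merge_partition()]; `merge_kappa = 0` disables the merge pass.
#' @return data.frame of segments with trial identifiers, phase labels and
#'   bend handedness attached.
#' @export
detect_segments <- function(trial, penalty_c = 1.25, speed_threshold = 50,
                            min_samples = 12, edge_trim = 3,
                            merge_kappa = NULL, merge_slope_gate = 25,
                            merge_jump_gate = 1) {
  stopifnot(inherits(trial, "aligned_trial"))
  g <- trial$gaze
  valid <- !g$excluded & is.finite(g$gh_deg) & is.finite(g$gv_deg)
  if (!any(valid)) return(empty_segments())
  r <- rle(valid)
  stops <- cumsum(r$lengths)
  starts <- stops - r$lengths + 1L
  out <- list()
  for (w in which(r$values)) {
    idx <- starts[w]:stops[w]
    if (length(idx) < max(min_samples, 2L)) next
    pen <- select_penalty(g$gh_deg[idx], g$gv_deg[idx], c = penalty_c)
    sol <- partition_signal(g$t[idx], g$gh_deg[idx], g$gv_deg[idx], pen)
    if (is.null(merge_kappa) || merge_kappa > 0) {
      sol <- merge_partition(sol, g$t[idx], g$gh_deg[idx], g$gv_deg[idx],
                             kappa = merge_kappa,
                             slope_gate = merge_slope_gate,
                             jump_gate = merge_jump_gate)
    }
    seg <- classify_segments(sol, g$t[idx], g$gh_deg[idx], g$gv_deg[idx],
                             yaw = g$yaw_dps[idx],
                             speed_threshold = speed_threshold,
                             min_samples = min_samples,
                             edge_trim = edge_trim)
    mid <- idx[floor((sol$breaks + sol$ends) / 2)]
    seg$phase <- g$phase[mid]
    out[[length(out) + 1L]] <- seg
  }
  if (!length(out)) return(empty_segments())
  seg <- do.call(rbind, out)
  seg$subject <- trial$meta$subject %||% NA_character_
  seg$trial <- trial$meta$trial %||% NA_integer_
  seg$condition <- trial$meta$condition %||% NA_character_
  bend <- trial$meta$bend
  seg$bend <- if (is.null(bend)) NA_character_ else bend$id
  seg$handedness <- if (is.null(bend)) "right" else bend$handedness
  seg[, c("subject", "trial", "condition", "bend", "handedness", "phase",
          "t_start", "t_end", "duration", "n", "slope_h", "slope_v",
          "amp_h", "amp_v", "speed", "direction", "class", "yaw_mean")]
}

empty_segments <- function() {
  data.frame(subject = character(), trial = integer(), condition = character(),
             bend = character(), handedness = character(), phase = character(),
             t_start = numeric(), t_end = numeric(), duration = numeric(),
             n = integer(), slope_h = numeric(), slope_v = numeric(),
             amp_h = numeric(), amp_v = numeric(), speed = numeric(),
             direction = numeric(), class = character(), yaw_mean = numeric())
}

#' Write / read a segment table as TSV
#' @param segments data.frame from [detect_segments()].
#' @param path TSV file path.
#' @return `write_segments_tsv` returns `path` invisibly.
#' @export
write_segments_tsv <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_segments_tsv
#' @export
read_segments_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
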
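# Descriptive summaries and the fixation-by-fixation velocity statistic
# with per-subject aggregation and condition contrasts.
#
# The central quantity is, for each detected slow phase during cornering,
#
#   Delta = 1/2 * |mean yaw rate over the segment| - v_against
#
# where v_against is the horizontal slow-phase velocity component directed
# AGAINST the bend (positive when gaze moves opposite to the turn). Under
# perfect waypoint tracking the line of sight rotates against the bend at
# half the yaw rate, so Delta centres on zero; under perfect tangent-point
# fixation gaze does not move horizontally and Delta equals +1/2 |yaw|.
# This orientation (tangent-point condition positive) is a package
# convention: with it, instructed tangent-point fixation produces a
# positive group mean while free driving stays near zero.

#' Gaze displacement from the tangent point
#'
#' Per-sample displacement of gaze from the tangent-point direction
#' (gaze minus TP, per axis) over the cornering phase, plus the
#' component-wise median, the robust per-subject summary used to place
#' individuals on gaze-distribution maps.
#'
#' @param trial an `aligned_trial`.
#' @param eye_height eye height (m) for the TP vertical direction.
#' @return list with `samples` (data.frame `t`, `dh`, `dv` over included
#'   cornering samples) and `median` (named numeric, `dh`/`dv`).
#' @export
tp_displacement <- function(trial, eye_height = trial$meta$eye_height %||% 1.2) {
  stopifnot(inherits(trial, "aligned_trial"))
  g <- trial$gaze
  keep <- g$phase == "cornering" & !g$excluded
  if (!any(keep)) {
    return(list(samples = data.frame(t = numeric(), dh = numeric(),
                                     dv = numeric()),
                median = c(dh = NA_real_, dv = NA_real_)))
  }
  # During cornering the heading is perpendicular to the center radius, so
  # the TP direction reduces to the closed form 90 - asin(R/d): it needs
  # only the distance d from the bend center. In synthetic trials d is the
  # driven radius (geometric ground truth); positions reconstructed from
  # the 1 Hz GPS channel are only a fallback, since linear interpolation
  # between GPS fixes cuts the corner and biases d low.
  bend <- trial$meta$bend
  R <- bend$inner_edge_radius
  d <- if (!is.null(trial$meta$path_radius)) {
    rep(trial$meta$path_radius, sum(keep))
  } else {
    sqrt((g$x_m[keep] - bend$center[1])^2 +
           (g$y_m[keep] - bend$center[2])^2)
  }
  d <- pmax(d, R + 1e-6)
  sgn <- if (bend$handedness == "right") 1 else -1
  tp_h <- sgn * (90 - asin(R / d) * RAD2DEG)
  tp_v <- atan(eye_height / sqrt(d^2 - R^2)) * RAD2DEG
  dh <- g$gh_deg[keep] - tp_h
  dv <- g$gv_deg[keep] - tp_v
  list(samples = data.frame(t = g$t[keep], dh = dh, dv = dv),
       median = c(dh = stats::median(dh), dv = stats::median(dv)))
}

#' Relative-frequency histogram of slow-phase directions
#'
#' Equal-width angular bins over (-180, 180]; 0 deg is vehicle-frame
#' upward, positive clockwise (the convention of [segment_velocity()]).
#' Frequencies sum to one.
#'
#' @param segments segment table; only rows with `class == "slow_phase"`
#'   are used.
#' @param n_bins number of bins.
#' @return data.frame with `bin_mid`, `bin_lo`, `bin_hi` (deg), `freq`.
#' @export
direction_histogram <- function(segments, n_bins = 36) {
  sp <- segments[segments$class == "slow_phase", , drop = FALSE]
  if (nrow(sp) == 0) stop("empty histogram error: no slow-phase segments")
  edges <- seq(-180, 180, length.out = n_bins + 1)
  # bins are (lo, hi]; directions are already wrapped to (-180, 180]
  idx <- findInterval(sp$direction, edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  idx[idx == 0L] <- 1L
  counts <- tabulate(idx, nbins = n_bins)
  data.frame(bin_lo = edges[-(n_bins + 1)], bin_hi = edges[-1],
             bin_mid = (edges[-(n_bins + 1)] + edges[-1]) / 2,
             freq = counts / sum(counts))
}

#' Fixation-by-fixation velocity statistic
#'
#' Computes Delta = 1/2 |mean yaw| - v_against for every slow-phase segment
#' in the cornering phase, where v_against is the horizontal gaze velocity
#' against the bend direction (for a right-hand bend, leftward gaze motion
#' is against the bend).
#'
#' @param segments segment table from [detect_segments()] (needs
#'   `handedness` and `yaw_mean`).
#' @return data.frame of per-segment statistics: subject, trial, condition,
#'   bend, `v_against`, `half_yaw`, `delta` (deg/s). Segments outside the
#'   cornering phase or not slow phases are skipped.
#' @export
velocity_statistic <- function(segments) {
  sp <- segments[segments$class == "slow_phase" &
                   segments$phase == "cornering" &
                   is.finite(segments$yaw_mean), , drop = FALSE]
  if (nrow(sp) == 0) return(data.frame(subject = character(),
                                       trial = integer(),
                                       condition = character(),
                                       bend = character(),
                                       v_against = numeric(),
                                       half_yaw = numeric(),
                                       delta = numeric()))
  sgn <- ifelse(sp$handedness == "right", -1, 1)
  v_against <- sgn * sp$slope_h
  half_yaw <- abs(sp$yaw_mean) / 2
  data.frame(subject = sp$subject, trial = sp$trial, condition = sp$condition,
             bend = sp$bend, v_against = v_against, half_yaw = half_yaw,
             delta = half_yaw - v_against)
}

#' Per-subject aggregation and condition contrasts
#'
#' Aggregates per-segment Delta statistics to per-subject means within each
#' condition and computes: a t-based 95% confidence interval for each
#' condition's group mean (df = n - 1); a paired two-sided t-test of
#' normal vs tp within subjects; an independent two-sample t-test with
#' pooled variance of normal vs control; and a pooled confidence interval
#' over the concatenated normal + control subject means.
#'
#' @param seg_stats data.frame from [velocity_statistic()].
#' @param conf_level confidence level (default 0.95).
#' @return object of class `group_result`: list with `per_subject`,
#'   `groups` (mean, ci_lo, ci_hi, n per condition), `paired_normal_tp`,
#'   `independent_normal_control`, `pooled_ci`, `conf_level`.
#' @export
group_inference <- function(seg_stats, conf_level = 0.95) {
  if (nrow(seg_stats) == 0) stop("no segment statistics to aggregate")
  per_subject <- stats::aggregate(delta ~ subject + condition,
                                  data = seg_stats, FUN = mean)
  names(per_subject)[names(per_subject) == "delta"] <- "mean_delta"

  ci_of <- function(x) {
    n <- length(x)
    m <- mean(x)
    if (n < 2) return(c(mean = m, ci_lo = NA_real_, ci_hi = NA_real_, n = n))
    hw <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1) *
      stats::sd(x) / sqrt(n)
    c(mean = m, ci_lo = m - hw, ci_hi = m + hw, n = n)
  }
  conds <- unique(per_subject$condition)
  groups <- do.call(rbind, lapply(conds, function(cc) {
    v <- ci_of(per_subject$mean_delta[per_subject$condition == cc])
    data.frame(condition = cc, mean = v["mean"], ci_lo = v["ci_lo"],
               ci_hi = v["ci_hi"], n = v["n"], row.names = NULL)
  }))

  paired <- NULL
  if (all(c("normal", "tp") %in% conds)) {
    nn <- per_subject[per_subject$condition == "normal", ]
    tt <- per_subject[per_subject$condition == "tp", ]
    common <- intersect(nn$subject, tt$subject)
    if (length(common) >= 2) {
      a <- nn$mean_delta[match(common, nn$subject)]
      b <- tt$mean_delta[match(common, tt$subject)]
      # hand-rolled so that zero-variance differences give t = 0 (or +-Inf)
      # rather than an error
      d <- b - a
      nd <- length(d)
      se <- stats::sd(d) / sqrt(nd)
      tstat <- if (se == 0) {
        if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      } else mean(d) / se
      hw <- stats::qt(1 - (1 - conf_level) / 2, nd - 1) * se
      paired <- list(t = tstat, df = nd - 1L,
                     p = 2 * stats::pt(-abs(tstat), nd - 1),
                     ci = mean(d) + c(-hw, hw),
                     mean_difference = mean(d))
    }
  }

  indep <- NULL
  if (all(c("normal", "control") %in% conds)) {
    a <- per_subject$mean_delta[per_subject$condition == "normal"]
    b <- per_subject$mean_delta[per_subject$condition == "control"]
    if (length(a) >= 2 && length(b) >= 2) {
      ht <- stats::t.test(a, b, var.equal = TRUE, conf.level = conf_level)
      indep <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                    p = ht$p.value, ci = unname(ht$conf.int),
                    mean_difference = unname(diff(rev(ht$estimate))))
    }
  }

  pooled <- NULL
  pool_conds <- intersect(c("normal", "control"), conds)
  if (length(pool_conds)) {
    x <- per_subject$mean_delta[per_subject$condition %in% pool_conds]
    if (length(x) >= 2) {
      v <- ci_of(x)
      pooled <- list(mean = unname(v["mean"]), ci = unname(v[c("ci_lo", "ci_hi")]),
                     n = unname(v["n"]))
    }
  }

  if (sum(groups$n) < 2) stop("CI undefined error: need at least 2 subjects")
  structure(list(per_subject = per_subject, groups = groups,
                 paired_normal_tp = paired,
                 independent_normal_control = indep,
                 pooled_ci = pooled, conf_level = conf_level),
            class = "group_result")
}

#' @export
print.group_result <- function(x, ...) {
  cat("<group_result>\n")
  for (i in seq_len(nrow(x$groups))) {
    g <- x$groups[i, ]
    cat(sprintf("  %-8s mean Delta = %6.2f deg/s, %d%% CI [%.2f, %.2f], n = %d\n",
                g$condition, g$mean, round(100 * x$conf_level), g$ci_lo,
                g$ci_hi, g$n))
  }
  if (!is.null(x$paired_normal_tp)) {
    p <- x$paired_normal_tp
    cat(sprintf("  paired tp - normal: t(%d) = %.2f, p = %.3g\n",
                p$df, p$t, p$p))
  }
  if (!is.null(x$independent_normal_control)) {
    p <- x$independent_normal_control
    cat(sprintf("  normal - control (pooled var): t(%d) = %.2f, p = %.3g\n",
                p$df, p$t, p$p))
  }
  if (!is.null(x$pooled_ci)) {
    cat(sprintf("  pooled normal+control CI [%.2f, %.2f], n = %d\n",
                x$pooled_ci$ci[1], x$pooled_ci$ci[2], x$pooled_ci$n))
  }
  invisible(x)
}

#' Highest-density-region thresholds for 2-D velocity samples
#'
#' Kernel density estimate (axis-wise normal reference bandwidths) on a
#' grid; for each requested probability mass the density level whose
#' superlevel set contains that fraction of the samples (nearest
#' achievable) is returned, as used for level curves enclosing 25/50/75%
#' of measurements.
#'
#' @param vh,vv sample coordinates (e.g. horizontal/vertical slow-phase
#'   velocities, deg/s); at least 30 samples.
#' @param mass fractions in (0, 1\].
#' @param grid_n KDE grid resolution per axis.
#' @return data.frame with `mass`, `level` (density threshold) and
#'   `achieved` (fraction of samples at or above the threshold).
#' @export
hdr_mass_threshold <- function(vh, vv, mass = c(0.25, 0.5, 0.75),
                               grid_n = 101) {
  n <- length(vh)
  stopifnot(length(vv) == n)
  if (n < 30) stop("need at least 30 samples for a density estimate")
  if (any(mass <= 0 | mass > 1)) stop("mass fractions must be in (0, 1]")
  h <- c(MASS::bandwidth.nrd(vh), MASS::bandwidth.nrd(vv))
  h[h <= 0] <- 0.1
  pad <- 2 * h
  kd <- MASS::kde2d(vh, vv, h = h, n = grid_n,
                    lims = c(range(vh) + c(-1, 1) * pad[1],
                             range(vv) + c(-1, 1) * pad[2]))
  # density at each sample: nearest grid cell (grid is fine relative to h)
  ix <- findInterval(vh, kd$x, all.inside = TRUE)
  iy <- findInterval(vv, kd$y, all.inside = TRUE)
  # snap to the nearer of the two bracketing grid lines
  ix <- ix + (vh - kd$x[ix] > diff(kd$x[1:2]) / 2)
  iy <- iy + (vv - kd$y[iy] > diff(kd$y[1:2]) / 2)
  dens <- kd$z[cbind(ix, iy)]
  sorted <- sort(dens, decreasing = TRUE)
  out <- lapply(mass, function(p) {
    k <- max(1L, min(n, ceiling(p * n)))
    lev <- sorted[k]
    data.frame(mass = p, level = lev, achieved = mean(dens >= lev))
  })
  do.call(rbind, out)
}

#' Classify each trial's gaze strategy from its Delta statistic
#'
#' A trial is called tangent-point-like when its mean Delta exceeds half of
#' the tangent-point prediction (i.e. Delta > 1/4 |yaw|, the midpoint
#' between the waypoint prediction 0 and the tangent-point prediction
#' 1/2 |yaw|), and waypoint-like otherwise.
#'
#' @param seg_stats data.frame from [velocity_statistic()].
#' @return data.frame with one row per trial: subject, trial, condition,
#'   `mean_delta`, `mean_half_yaw`, `predicted` (`"tp"`/`"normal"`),
#'   `correct` (predicted matches condition, with `control` counted as
#'   normal driving).
#' @export
classify_trial_strategy <- function(seg_stats) {
  if (nrow(seg_stats) == 0) stop("no segment statistics")
  agg <- stats::aggregate(cbind(delta, half_yaw) ~ subject + trial + condition,
                          data = seg_stats, FUN = mean)
  names(agg)[names(agg) == "delta"] <- "mean_delta"
  names(agg)[names(agg) == "half_yaw"] <- "mean_half_yaw"
  agg$predicted <- ifelse(agg$mean_delta > agg$mean_half_yaw / 2, "tp", "normal")
  truth <- ifelse(agg$condition == "tp", "tp", "normal")
  agg$correct <- agg$predicted == truth
  agg
}
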
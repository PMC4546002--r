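# Tangent-point displacement, direction histograms, the Delta statistic
# and group inference.

test_that("tp displacement is zero for a noiseless tangent-point trial", {
  tr <- noiseless_trial("tp", seed = 81)
  al <- align_trial(tr)
  disp <- tp_displacement(al)
  expect_equal(unname(disp$median), c(0, 0), tolerance = 1e-6)
})

test_that("waypoint gaze is displaced from the TP by the waypoint-TP gap", {
  tr <- noiseless_trial("waypoint", seed = 82)
  al <- align_trial(tr)
  disp <- tp_displacement(al)
  # geometry oracle: waypoint minus tangent-point direction at preview 2 s.
  # At this preview the on-path waypoint sits between the heading and the
  # TP, so the signed gap is negative; longer previews move it past the TP.
  st <- vehicle_state_at(default_bend(), 48, paper_speed, t = 1)
  wp <- path_point(default_bend(), 48, st$arc_position + 2 * paper_speed)
  gap <- waypoint_direction(st, wp)$horizontal -
    tangent_point_direction(st, default_bend())$horizontal
  expect_gt(abs(disp$median["dh"]), 0.5)
  expect_equal(sign(unname(disp$median["dh"])), sign(gap))
  # gaze decays from the acquisition direction by up to 1/2 yaw x SP
  # duration within each slow phase, so the median sits below the gap
  decay <- 0.5 * (paper_speed / 48) * 180 / pi * 0.45
  expect_lt(abs(unname(disp$median["dh"]) - (gap - decay / 2)), decay)
  # medians barely move under white noise
  pars <- strategy_params("waypoint", noise_sd = 0.7, vibration_sd = 0,
                          dropout_prob = 0)
  trn <- add_sensor_noise(noiseless_trial("waypoint", seed = 82), pars,
                          seed = 83)
  dispn <- tp_displacement(align_trial(trn))
  expect_lt(abs(dispn$median["dh"] - disp$median["dh"]), 0.12)
})

test_that("direction histograms are normalised and locate the flow quadrant", {
  seg <- data.frame(direction = rep(0, 5), class = "slow_phase")
  h <- direction_histogram(seg, n_bins = 8)
  expect_equal(sum(h$freq), 1, tolerance = 1e-12)
  expect_equal(sum(h$freq > 0), 1)
  # normalisation is exact for any bin count
  set.seed(601)
  seg2 <- data.frame(direction = runif(500, -180, 180), class = "slow_phase")
  for (nb in c(8, 36, 71)) {
    expect_equal(sum(direction_histogram(seg2, nb)$freq), 1,
                 tolerance = 1e-12)
  }
  expect_error(direction_histogram(seg2[0, ], 8), "empty histogram")
  # synthetic waypoint cohort: modal direction against the bend and downward
  tr <- noiseless_trial("waypoint", seed = 84)
  segs <- detect_segments(align_trial(tr))
  segs <- segs[segs$phase == "cornering", ]
  hh <- direction_histogram(segs, n_bins = 8)
  modal <- hh$bin_mid[which.max(hh$freq)]
  expect_true(modal < -90 & modal >= -180)  # left and down quadrant
})

test_that("Delta is zero for waypoint tracking and +half-yaw for TP fixation", {
  base <- data.frame(subject = "s1", trial = 1L, condition = "normal",
                     bend = "b", handedness = "right", phase = "cornering",
                     class = "slow_phase", yaw_mean = -13.93,
                     stringsAsFactors = FALSE)
  # perfect waypoint tracking: leftward slope at half yaw
  wp <- transform(base, slope_h = -13.93 / 2)
  expect_equal(velocity_statistic(wp)$delta, 0, tolerance = 1e-9)
  # perfect tangent-point fixation: no horizontal movement
  tp <- transform(base, slope_h = 0)
  expect_equal(velocity_statistic(tp)$delta, 13.93 / 2, tolerance = 1e-9)
  # hypothetical over-tracking at the full yaw rate
  over <- transform(base, slope_h = -13.93)
  expect_equal(velocity_statistic(over)$delta, -13.93 / 2, tolerance = 1e-9)
  # left-hand mirror image gives identical Delta
  left <- transform(base, handedness = "left", slope_h = 13.93 / 2,
                    yaw_mean = 13.93)
  expect_equal(velocity_statistic(left)$delta,
               velocity_statistic(wp)$delta, tolerance = 1e-12)
  # segments outside cornering are skipped
  out <- transform(base, slope_h = 0, phase = "entry")
  expect_equal(nrow(velocity_statistic(out)), 0)
})

test_that("Delta distributions are invariant under bend mirroring", {
  pars <- noiseless_params("waypoint")
  bl <- bend_geometry(handedness = "left")
  tr_r <- simulate_trial(default_bend(), pars, speed = paper_speed, seed = 85)
  tr_l <- simulate_trial(bl, pars, speed = paper_speed, seed = 85)
  d_r <- velocity_statistic(detect_segments(align_trial(tr_r)))$delta
  d_l <- velocity_statistic(detect_segments(align_trial(tr_l)))$delta
  expect_equal(d_r, d_l, tolerance = 1e-6)
})

test_that("group inference matches hand-computed t formulas", {
  mk <- function(subj, cond, deltas) {
    data.frame(subject = subj, trial = seq_along(deltas), condition = cond,
               bend = "b", v_against = 0, half_yaw = 7, delta = deltas)
  }
  # subject means {1, 2, 3}: mean 2, CI 2 +- 4.303 / sqrt(3)
  stats3 <- rbind(mk("a", "normal", 1), mk("b", "normal", 2),
                  mk("c", "normal", 3))
  gr <- group_inference(stats3)
  g <- gr$groups
  expect_equal(g$mean, 2)
  expect_equal(g$ci_lo, 2 - 4.302653 * 1 / sqrt(3), tolerance = 1e-5)
  expect_equal(g$ci_hi, 2 + 4.302653 * 1 / sqrt(3), tolerance = 1e-5)
  expect_equal(g$ci_lo, -0.484, tolerance = 1e-3)
  # identical normal and tp means: paired t exactly zero
  both <- rbind(stats3, mk("a", "tp", 1), mk("b", "tp", 2), mk("c", "tp", 3))
  expect_equal(group_inference(both)$paired_normal_tp$t, 0, tolerance = 1e-12)
  expect_equal(group_inference(both)$paired_normal_tp$df, 2)
  # independent contrast uses the pooled-variance df n1 + n2 - 2
  withc <- rbind(stats3, mk("x", "control", 1.5), mk("y", "control", 2.5),
                 mk("z", "control", 2))
  gi <- group_inference(withc)
  expect_equal(gi$independent_normal_control$df, 4)
  # hand-computed pooled t for these groups
  a <- c(1, 2, 3); b <- c(1.5, 2.5, 2)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_hand <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(gi$independent_normal_control$t, t_hand, tolerance = 1e-9)
  # pooled CI covers the concatenated normal + control means
  pooled <- gi$pooled_ci
  x <- c(a, b)
  expect_equal(pooled$mean, mean(x))
  expect_equal(pooled$ci[1],
               mean(x) - qt(0.975, 5) * sd(x) / sqrt(6), tolerance = 1e-9)
  expect_error(group_inference(mk("a", "normal", 1)), "2 subjects")
})

test_that("HDR thresholds enclose the requested mass of a bivariate normal", {
  set.seed(602)
  n <- 5000
  vh <- rnorm(n); vv <- rnorm(n)
  hdr <- hdr_mass_threshold(vh, vv, mass = c(0.25, 0.5, 0.75, 1))
  expect_lt(abs(hdr$achieved[hdr$mass == 0.5] - 0.5), 0.03)
  expect_lt(abs(hdr$achieved[hdr$mass == 0.25] - 0.25), 0.03)
  # monotonicity: more mass needs a lower density level
  expect_true(all(diff(hdr$level) < 0))
  # p = 1 threshold is at or below the least dense sample
  expect_lte(hdr$level[hdr$mass == 1], min(hdr$level))
  expect_error(hdr_mass_threshold(rnorm(10), rnorm(10)), "30 samples")
})
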
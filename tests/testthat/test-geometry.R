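# Closed-form cornering geometry: tangent-point constancy, the
# half-yaw-rate rotation law, and egocentric sign conventions.

wrap_heading_diff <- function(a, b) (a - b + 180) %% 360 - 180

test_that("vehicle state on the arc has the right kinematics", {
  b <- default_bend()
  st0 <- vehicle_state_at(b, path_radius = 48, speed = 11.67, t = 0)
  expect_equal(st0$arc_position, 0)
  onset <- path_point(b, 48, 0)
  expect_equal(c(st0$x, st0$y), unname(onset[1, ]), tolerance = 1e-12)
  # yaw-rate magnitude = (v / r) in deg/s, independently recomputed
  expect_equal(st0$yaw_rate, (11.67 / 48) * 180 / pi, tolerance = 1e-12)
  expect_equal(st0$yaw_rate, 13.93, tolerance = 1e-3)
  # quarter circle -> heading rotated 90 degrees
  tq <- (pi / 2 * 48) / 11.67
  b_full <- bend_geometry(arc_span = 150)
  stq <- vehicle_state_at(b_full, 48, 11.67, tq)
  expect_equal(abs(wrap_heading_diff(stq$heading, st0$heading)), 90,
               tolerance = 1e-9)
  # position stays on the path circle
  expect_equal(sqrt(stq$x^2 + stq$y^2), 48, tolerance = 1e-9)
  expect_error(vehicle_state_at(b, 48, 11.67, t = 1e4), "out-of-bend")
  expect_error(vehicle_state_at(b, path_radius = 10, speed = 10, t = 0),
               "geometry error")
})

test_that("tangent point direction matches the arcsin closed form and is constant", {
  b <- bend_geometry(inner_edge_radius = 48, lane_width = 4)
  st <- vehicle_state_at(b, path_radius = 50, speed = 11.67, t = 0)
  tp <- tangent_point_direction(st, b)
  expect_equal(tp$horizontal, 90 - asin(48 / 50) * 180 / pi, tolerance = 1e-9)
  expect_equal(tp$horizontal, 16.26, tolerance = 1e-2)
  # constancy over a 10 s concentric traversal
  sts <- vehicle_state_at(b, 50, speed = 5, t = seq(0, 10, by = 0.05))
  tps <- tangent_point_direction(sts, b)
  expect_lt(diff(range(tps$horizontal)), 1e-9)
  # limit: vehicle on the inner edge circle -> direction 0
  b2 <- bend_geometry(inner_edge_radius = 48, lane_width = 4)
  st_lim <- vehicle_state_at(b2, path_radius = 48 + 1e-9, speed = 10, t = 0)
  expect_lt(abs(tangent_point_direction(st_lim, b2)$horizontal), 1e-3)
  # inside the edge circle the TP does not exist
  st_bad <- st
  st_bad$x <- 0; st_bad$y <- 10
  expect_error(tangent_point_direction(st_bad, b), "undefined-TP")
})

test_that("waypoint direction follows the half-arc inscribed-angle relation", {
  b <- default_bend()
  r <- 48
  st <- vehicle_state_at(b, r, speed = 11.67, t = 0)
  # remaining arc 90 deg -> 45 deg; 60 -> 30; degenerate limit -> 0
  for (arc in c(90, 60, 10, 1)) {
    wp <- path_point(b, r, arc_position = arc * pi / 180 * r)
    expect_equal(waypoint_direction(st, wp)$horizontal, arc / 2,
                 tolerance = 1e-9)
  }
  # direct atan2 construction equals the half-arc formula for 1000 random
  # configurations (radius, speed, vehicle position, remaining arc)
  set.seed(401)
  for (k in 1:1000) {
    rr <- runif(1, 20, 120)
    bb <- bend_geometry(inner_edge_radius = rr - 2, lane_width = 4,
                        arc_span = 170,
                        handedness = sample(c("right", "left"), 1))
    sp <- runif(1, 5, 30)
    t0 <- runif(1, 0, 0.3 * cornering_arc_length(bb, rr) / sp)
    stv <- vehicle_state_at(bb, rr, sp, t0)
    gamma <- runif(1, 1, 150)
    wp <- path_point(bb, rr, stv$arc_position + gamma * pi / 180 * rr)
    expect_equal(abs(waypoint_direction(stv, wp)$horizontal), gamma / 2,
                 tolerance = 1e-8)
  }
  # waypoint behind the vehicle violates the precondition
  behind <- path_point(b, r, -30)
  expect_error(waypoint_direction(st, behind), "behind")
})

test_that("lines of sight to on-path points rotate at minus half the yaw rate", {
  set.seed(402)
  for (k in 1:50) {
    r <- runif(1, 25, 100)
    sp <- runif(1, 5, 25)
    hand <- sample(c("right", "left"), 1)
    b <- bend_geometry(inner_edge_radius = r - 2, lane_width = 4,
                       arc_span = 160, handedness = hand)
    st <- vehicle_state_at(b, r, sp, t = runif(1, 0, 1))
    gamma <- runif(1, 5, 140)
    wp <- path_point(b, r, st$arc_position + gamma * pi / 180 * r)
    rate <- gaze_angle_rate(st, wp)
    expected <- -0.5 * st$yaw_rate * (if (hand == "right") 1 else -1)
    expect_equal(rate, expected, tolerance = 1e-9)
    # the 2:1 observer-to-eye rotation ratio, sign toward the bend
    expect_equal(st$yaw_rate / abs(rate), 2, tolerance = 1e-9)
    if (hand == "right") expect_lt(rate, 0) else expect_gt(rate, 0)
  }
})

test_that("gaze angle rate matches a central finite difference for off-path points", {
  b <- default_bend()
  pts <- rbind(c(30, 40), c(-20, 60), c(55, 10), c(10, 80))
  dt <- 1e-3
  for (i in seq_len(nrow(pts))) {
    st <- vehicle_state_at(b, 48, 11.67, t = 2)
    st2 <- vehicle_state_at(b, 48, 11.67, t = c(2 - dt / 2, 2 + dt / 2))
    fd <- diff(egocentric_direction(st2, matrix(pts[i, ], 2, 2,
                                                byrow = TRUE))$horizontal) / dt
    expect_equal(gaze_angle_rate(st, pts[i, ]), fd, tolerance = 1e-6)
  }
  # straight driving, point dead ahead: no rotation
  st_straight <- data.frame(t = 0, x = 0, y = 0, heading = 0, speed = 10,
                            yaw_rate = 0, heading_rate = 0,
                            path_radius = Inf, arc_position = 0)
  expect_equal(gaze_angle_rate(st_straight, c(100, 0)), 0, tolerance = 1e-12)
})

test_that("sign conventions: right-hand bend has TP right, flow left", {
  b <- default_bend()  # right-handed
  st <- vehicle_state_at(b, 48, 11.67, t = 1)
  expect_gt(tangent_point_direction(st, b)$horizontal, 0)
  wp <- path_point(b, 48, st$arc_position + 30)
  expect_lt(gaze_angle_rate(st, wp), 0)
  # mirrored bend mirrors both signs
  bl <- bend_geometry(handedness = "left")
  stl <- vehicle_state_at(bl, 48, 11.67, t = 1)
  expect_lt(tangent_point_direction(stl, bl)$horizontal, 0)
  wpl <- path_point(bl, 48, stl$arc_position + 30)
  expect_gt(gaze_angle_rate(stl, wpl), 0)
})

test_that("vertical direction follows atan(eye height / distance) and grows on approach", {
  st <- data.frame(t = 0, x = 0, y = 0, heading = 0, speed = 10,
                   yaw_rate = 0, heading_rate = 0, path_radius = Inf,
                   arc_position = 0)
  expect_equal(vertical_direction(st, c(12, 0), eye_height = 1.2),
               atan(0.1) * 180 / pi, tolerance = 1e-12)
  expect_equal(vertical_direction(st, c(12, 0), eye_height = 1.2), 5.71,
               tolerance = 1e-2)
  # horizon limit
  expect_lt(vertical_direction(st, c(1e8, 0), eye_height = 1.2), 1e-5)
  # approaching a fixed point: strictly increasing
  xs <- seq(0, 90, by = 10)
  sts <- data.frame(t = xs / 10, x = xs, y = 0, heading = 0, speed = 10,
                    yaw_rate = 0, heading_rate = 0, path_radius = Inf,
                    arc_position = xs)
  v <- vertical_direction(sts, c(100, 0), eye_height = 1.2)
  expect_true(all(diff(v) > 0))
  expect_error(vertical_direction(st, c(0, 0), eye_height = 1.2),
               "zero distance")
  expect_error(vertical_direction(st, c(10, 0), eye_height = -1), "eye_height")
})

test_that("bend geometry validates its invariants and round-trips JSON", {
  expect_error(bend_geometry(inner_edge_radius = -1), "inner_edge_radius")
  expect_error(bend_geometry(arc_span = 0), "arc_span")
  expect_error(bend_geometry(exit_cutoff = 1e4), "exit_cutoff")
  b <- bend_geometry(inner_edge_radius = 46, lane_width = 4, arc_span = 130)
  expect_equal(mid_lane_radius(b), 48)
  f <- tempfile(fileext = ".json")
  write_bend_json(b, f)
  b2 <- read_bend_json(f)
  expect_equal(b2, b)
  unlink(f)
})
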
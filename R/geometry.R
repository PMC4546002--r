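# Closed-form kinematics and egocentric visual geometry of constant-radius
# cornering.
#
# Conventions (used throughout the package):
#   * Allocentric frame: right-handed planar coordinates in metres; headings
#     are degrees counterclockwise from the +x axis.
#   * Egocentric horizontal angle: degrees, positive to the RIGHT of the
#     current heading. In a right-hand bend the tangent point therefore has a
#     positive horizontal direction, and the lines of sight to points on the
#     future path rotate negatively (leftward, against the bend).
#   * Egocentric vertical angle: degrees, positive BELOW the horizon.
#   * Yaw rate is reported in deg/s, signed positive when the vehicle turns
#     toward the bend; the allocentric heading rate (CCW positive) is kept
#     alongside it so angular rates of lines of sight can be formed without
#     knowing the bend handedness.

#' Define a constant-radius bend
#'
#' A parametric description of a one-lane constant-radius bend: a circular
#' inner lane edge of radius `inner_edge_radius` about `center`, a lane of
#' width `lane_width`, and a cornering phase spanning `arc_span` degrees.
#' The bend supplies ground truth for the tangent point (the point on the
#' inner edge where the line of sight is tangential to it) and for the
#' future path, and carries the analysis-phase parameters: the entry phase
#' starts `entry_length` metres before cornering onset, and the last
#' `exit_cutoff` metres of the cornering arc are excluded so that both the
#' vehicle and the gaze landing point stay on the constant-curvature
#' section.
#'
#' @param center numeric length-2, bend center in metres.
#' @param inner_edge_radius radius of the inner lane edge circle (m).
#' @param lane_width lane width (m); the default driven path runs mid-lane
#'   at radius `inner_edge_radius + lane_width / 2`.
#' @param arc_span angular span of the cornering phase (degrees, in (0, 360]).
#' @param handedness `"right"` or `"left"`.
#' @param entry_length length of the entry phase before cornering onset (m).
#' @param exit_cutoff length cut off the end of the cornering phase (m);
#'   35 m corresponds to roughly 3 s of travel at 42 km/h.
#' @param id optional bend identifier (character).
#' @return An object of class `bend_geometry`.
#' @examples
#' b <- bend_geometry()
#' mid_lane_radius(b)
#' @export
bend_geometry <- function(center = c(0, 0), inner_edge_radius = 46,
                          lane_width = 4, arc_span = 130,
                          handedness = c("right", "left"),
                          entry_length = 50, exit_cutoff = 35,
                          id = "bend2") {
  handedness <- match.arg(handedness)
  stopifnot(length(center) == 2, is.finite(center))
  if (!(inner_edge_radius > 0)) stop("inner_edge_radius must be > 0")
  if (!(lane_width > 0)) stop("lane_width must be > 0")
  if (!(arc_span > 0 && arc_span <= 360)) stop("arc_span must be in (0, 360]")
  if (entry_length < 0) stop("entry_length must be >= 0")
  if (exit_cutoff < 0) stop("exit_cutoff must be >= 0")
  path_r <- inner_edge_radius + lane_width / 2
  arc_len <- arc_span * DEG2RAD * path_r
  if (exit_cutoff >= arc_len) {
    stop("exit_cutoff must be smaller than the cornering arc length (",
         round(arc_len, 1), " m)")
  }
  structure(
    list(center = as.numeric(center),
         inner_edge_radius = inner_edge_radius,
         lane_width = lane_width,
         arc_span = arc_span,
         handedness = handedness,
         entry_length = entry_length,
         exit_cutoff = exit_cutoff,
         id = id),
    class = "bend_geometry")
}

#' @export
print.bend_geometry <- function(x, ...) {
  cat(sprintf(
    "<bend_geometry '%s'> %s-hand, inner edge R = %.1f m, lane %.1f m, arc %.0f deg\n",
    x$id, x$handedness, x$inner_edge_radius, x$lane_width, x$arc_span))
  cat(sprintf("  entry %g m before onset; exit cutoff %g m; center (%g, %g)\n",
              x$entry_length, x$exit_cutoff, x$center[1], x$center[2]))
  invisible(x)
}

#' Mid-lane path radius of a bend
#' @param bend a [bend_geometry()].
#' @return radius in metres.
#' @export
mid_lane_radius <- function(bend) bend$inner_edge_radius + bend$lane_width / 2

#' Cornering arc length at a given path radius
#' @param bend a [bend_geometry()].
#' @param path_radius driven radius (m); defaults to mid-lane.
#' @return arc length in metres.
#' @export
cornering_arc_length <- function(bend, path_radius = mid_lane_radius(bend)) {
  bend$arc_span * DEG2RAD * path_radius
}

#' Read / write bend geometry as JSON
#'
#' Lengths are metres and angles degrees, keys mirror the field names of
#' [bend_geometry()].
#' @param bend a [bend_geometry()].
#' @param path file path.
#' @return `read_bend_json` returns a [bend_geometry()]; `write_bend_json`
#'   returns `path` invisibly.
#' @export
write_bend_json <- function(bend, path) {
  jsonlite::write_json(unclass(bend), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_bend_json
#' @export
read_bend_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  bend_geometry(center = x$center,
                inner_edge_radius = x$inner_edge_radius,
                lane_width = x$lane_width,
                arc_span = x$arc_span,
                handedness = x$handedness,
                entry_length = x$entry_length,
                exit_cutoff = x$exit_cutoff,
                id = x$id %||% "bend")
}

# Sign of the bend: +1 when heading rotates CCW (left bend), -1 when CW
# (right bend), in the allocentric frame.
bend_ccw_sign <- function(bend) if (bend$handedness == "left") 1 else -1

#' Vehicle state during constant-radius cornering
#'
#' Places the vehicle on a circle of `path_radius` about the bend center,
#' `t` seconds (at constant `speed`) after cornering onset. Heading is
#' tangential to the path circle and the yaw-rate magnitude is
#' `speed / path_radius` (converted to deg/s), signed positive toward the
#' bend direction. Vectorised over `t`.
#'
#' @param bend a [bend_geometry()].
#' @param path_radius driven radius (m), must exceed the inner edge radius.
#' @param speed vehicle speed (m/s), > 0.
#' @param t time since cornering onset (s); must lie within the traversal
#'   time of the arc span.
#' @return A data.frame of class `vehicle_state` with columns `t`, `x`, `y`
#'   (m), `heading` (deg allocentric CCW), `speed` (m/s), `yaw_rate`
#'   (deg/s, positive toward the bend), `heading_rate` (deg/s, allocentric
#'   CCW), `path_radius`, `arc_position` (m along the path from onset).
#' @examples
#' st <- vehicle_state_at(bend_geometry(), path_radius = 48,
#'                        speed = 42 / 3.6, t = 0)
#' st$yaw_rate  # about 13.93 deg/s
#' @export
vehicle_state_at <- function(bend, path_radius = mid_lane_radius(bend),
                             speed, t) {
  if (!(path_radius > bend$inner_edge_radius)) {
    stop("geometry error: path_radius must exceed inner_edge_radius")
  }
  if (!(speed > 0)) stop("speed must be > 0")
  t_max <- cornering_arc_length(bend, path_radius) / speed
  if (any(t < 0 | t > t_max + 1e-9)) {
    stop("out-of-bend error: t outside [0, ", signif(t_max, 6), "] s")
  }
  s <- speed * t
  theta <- s / path_radius                      # traversed arc angle (rad)
  sgn <- bend_ccw_sign(bend)
  # Cornering onset has heading +x; the center sits on the bend side, so a
  # right-hand bend starts "north" of the center and proceeds clockwise, a
  # left-hand bend starts "south" of it and proceeds counterclockwise.
  phi <- sgn * (theta - pi / 2)
  x <- bend$center[1] + path_radius * cos(phi)
  y <- bend$center[2] + path_radius * sin(phi)
  heading <- wrap_deg((phi + sgn * pi / 2) * RAD2DEG)
  omega <- speed / path_radius * RAD2DEG
  data.frame(t = t, x = x, y = y, heading = heading, speed = speed,
             yaw_rate = omega, heading_rate = sgn * omega,
             path_radius = path_radius, arc_position = s)
}

# Construct a vehicle_state row "by hand" (used for straight segments and by
# the simulator). heading_rate is allocentric CCW deg/s.
vehicle_state <- function(x, y, heading, speed, yaw_rate = 0,
                          heading_rate = 0, path_radius = Inf,
                          arc_position = NA_real_, t = NA_real_) {
  data.frame(t = t, x = x, y = y, heading = heading, speed = speed,
             yaw_rate = yaw_rate, heading_rate = heading_rate,
             path_radius = path_radius, arc_position = arc_position)
}

#' Egocentric direction of a world point
#'
#' Horizontal angle (deg, positive right of heading) and, when `eye_height`
#' is given, the vertical angle (deg, positive below the horizon) of an
#' allocentric ground-plane point seen from the vehicle. Vectorised over
#' rows of `state`.
#'
#' @param state a `vehicle_state` data.frame (one or more rows).
#' @param point numeric length-2 allocentric point (m), or a matrix with one
#'   row per state row.
#' @param eye_height eye height above the ground plane (m), or `NULL` to
#'   skip the vertical component.
#' @return data.frame with columns `horizontal` and `vertical` (degrees).
#' @export
egocentric_direction <- function(state, point, eye_height = NULL) {
  p <- if (is.matrix(point)) point else matrix(point, nrow = nrow(state),
                                               ncol = 2, byrow = TRUE)
  dx <- unname(p[, 1] - state$x)
  dy <- unname(p[, 2] - state$y)
  bearing <- atan2(dy, dx) * RAD2DEG
  horizontal <- wrap_deg(state$heading - bearing)
  dist <- sqrt(dx^2 + dy^2)
  vertical <- if (is.null(eye_height)) {
    rep(0, length(dist))
  } else {
    if (any(dist == 0)) stop("vertical direction undefined at zero distance")
    atan(eye_height / dist) * RAD2DEG
  }
  data.frame(horizontal = horizontal, vertical = vertical)
}

#' Tangent-point visual direction
#'
#' Direction of the tangent point: the point on the inner lane edge where
#' the line of sight is tangential to the edge. For a vehicle at distance
#' `d` from the bend center the horizontal magnitude is
#' `90 - asin(inner_edge_radius / d)` degrees, signed toward the bend; on a
#' concentric circular trajectory it is constant over time (the tangent
#' point is a travel point, stationary in the visual field).
#'
#' @inheritParams egocentric_direction
#' @param bend a [bend_geometry()].
#' @param eye_height eye height (m) for the vertical component, or `NULL`.
#' @return data.frame with columns `horizontal`, `vertical` (deg).
#' @export
tangent_point_direction <- function(state, bend, eye_height = NULL) {
  dx <- state$x - bend$center[1]
  dy <- state$y - bend$center[2]
  d <- sqrt(dx^2 + dy^2)
  R <- bend$inner_edge_radius
  if (any(d <= R)) {
    stop("undefined-TP error: vehicle distance from bend center must exceed ",
         "inner_edge_radius")
  }
  # General construction via the tangency point itself; for a vehicle whose
  # heading is perpendicular to the center radius (any concentric circular
  # trajectory) this reduces to the closed form 90 - asin(R/d), signed
  # toward the bend.
  tpp <- tangent_point_position(state, bend)
  egocentric_direction(state, tpp, eye_height)
}

# Allocentric position of the tangent point seen from `state` (the tangency
# point of the line of sight on the inner-edge circle, on the bend side
# ahead of the vehicle).
tangent_point_position <- function(state, bend) {
  dx <- state$x - bend$center[1]
  dy <- state$y - bend$center[2]
  d <- sqrt(dx^2 + dy^2)
  R <- bend$inner_edge_radius
  if (any(d <= R)) stop("undefined-TP error")
  # Angle at the center between the vehicle radius vector and the tangency
  # radius vector.
  alpha <- acos(R / d)
  base <- atan2(dy, dx)
  sgn <- bend_ccw_sign(bend)
  # the tangency point ahead of the vehicle lies at base + sgn * alpha
  ang <- base + sgn * alpha
  cbind(x = bend$center[1] + R * cos(ang),
        y = bend$center[2] + R * sin(ang))
}

#' Direction of a waypoint ahead on the path
#'
#' Egocentric direction of a world-fixed point, required to lie ahead of
#' the vehicle (within 90 degrees of heading). For a waypoint on the
#' vehicle's own circular path at a remaining arc of `gamma` degrees, the
#' horizontal magnitude equals `gamma / 2` (the inscribed-angle relation),
#' signed toward the bend.
#'
#' @inheritParams egocentric_direction
#' @param waypoint numeric length-2 allocentric point (m), or matrix.
#' @return data.frame with columns `horizontal`, `vertical` (deg).
#' @export
waypoint_direction <- function(state, waypoint, eye_height = NULL) {
  dir <- egocentric_direction(state, waypoint, eye_height)
  if (any(abs(dir$horizontal) > 90 + 1e-9)) {
    stop("precondition error: waypoint lies behind the vehicle")
  }
  dir
}

#' Angular rate of the line of sight to a fixed point
#'
#' Time derivative (deg/s) of the egocentric horizontal direction of an
#' allocentrically stationary point, i.e. the horizontal optic-flow rate at
#' that point. For any point on the vehicle's own circular path this equals
#' minus half the yaw rate: the eye of a driver tracking such a waypoint
#' counter-rotates at half the rate the vehicle rotates, a 2:1 ratio that
#' holds regardless of which on-path point is fixated.
#'
#' @inheritParams egocentric_direction
#' @param fixed_point numeric length-2 allocentric point (m), or matrix.
#' @return numeric vector of rates (deg/s), one per state row.
#' @examples
#' b <- bend_geometry()
#' st <- vehicle_state_at(b, 48, speed = 42 / 3.6, t = 0)
#' wp <- path_point(b, 48, arc_position = 40)
#' gaze_angle_rate(st, wp) / st$yaw_rate  # -0.5
#' @export
gaze_angle_rate <- function(state, fixed_point) {
  p <- if (is.matrix(fixed_point)) fixed_point else {
    matrix(fixed_point, nrow = nrow(state), ncol = 2, byrow = TRUE)
  }
  dx <- p[, 1] - state$x
  dy <- p[, 2] - state$y
  vx <- state$speed * cos(state$heading * DEG2RAD)
  vy <- state$speed * sin(state$heading * DEG2RAD)
  r2 <- dx^2 + dy^2
  if (any(r2 == 0)) stop("gaze rate undefined at zero distance")
  bearing_rate <- (dy * vx - dx * vy) / r2 * RAD2DEG
  unname(state$heading_rate - bearing_rate)
}

#' Allocentric point on the cornering arc
#'
#' Position on the circle of `path_radius` about the bend center at
#' `arc_position` metres along the path from cornering onset.
#'
#' @param bend a [bend_geometry()].
#' @param path_radius driven radius (m).
#' @param arc_position distance along the arc from onset (m); vectorised.
#' @return matrix with columns `x`, `y`.
#' @export
path_point <- function(bend, path_radius = mid_lane_radius(bend),
                       arc_position) {
  sgn <- bend_ccw_sign(bend)
  phi <- sgn * (arc_position / path_radius - pi / 2)
  cbind(x = bend$center[1] + path_radius * cos(phi),
        y = bend$center[2] + path_radius * sin(phi))
}

#' Vertical direction of a ground point
#'
#' Vertical gaze angle below the horizon of a ground-plane point, from eye
#' height and ground distance: `atan(eye_height / distance)`. Increases
#' monotonically as the point is approached.
#'
#' @inheritParams egocentric_direction
#' @param ground_point numeric length-2 allocentric point (m), or matrix.
#' @param eye_height eye height above ground (m), > 0 (default 1.2).
#' @return numeric vector of vertical angles (deg, positive below horizon).
#' @export
vertical_direction <- function(state, ground_point, eye_height = 1.2) {
  if (!(eye_height > 0)) stop("eye_height must be > 0")
  p <- if (is.matrix(ground_point)) ground_point else {
    matrix(ground_point, nrow = nrow(state), ncol = 2, byrow = TRUE)
  }
  dist <- sqrt((p[, 1] - state$x)^2 + (p[, 2] - state$y)^2)
  if (any(dist == 0)) stop("vertical direction undefined at zero distance")
  atan(eye_height / dist) * RAD2DEG
}
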
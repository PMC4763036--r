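# Outbound-path kinematics and strategy-to-quadrant geometry.
#
# Frame convention (bird's-eye, right-handed): the observer starts at the
# origin facing +z; +x is to the right; headings are measured in degrees from
# the initial facing direction, positive clockwise (rightward). Left turns
# are therefore negative angles.

#' Quadrant and strategy level sets
#'
#' `quadrants()` returns the four egocentric answer quadrants (front-left,
#' front-right, back-left, back-right) as the codes used throughout the
#' package and in cohort CSV files. `strategies()` returns the four
#' hypothesised response strategies, and `classifications()` the five
#' participant-level classes (the strategies plus `"no-preference"` for
#' participants whose answers never reach the consistency criterion).
#'
#' @return A character vector of level codes.
#' @export
quadrants <- function() c("FL", "FR", "BL", "BR")

#' @rdname quadrants
#' @export
strategies <- function() c("turner", "non-turner", "non-mover", "spinner")

#' @rdname quadrants
#' @export
classifications <- function() c(strategies(), "no-preference")

#' Kinematic recipe for one outbound trial
#'
#' A path specification describes the five phases of the stimulus
#' trajectory: a linear acceleration up to cruise speed, a first constant
#' segment, a curve with a triangular angular-velocity profile (symmetric
#' angular acceleration and deceleration halves) at constant translational
#' speed, a second constant segment, and a linear deceleration to rest.
#'
#' Defaults follow the stimulus used in classroom studies of this task:
#' 1 s acceleration at 10 m/s^2 to a 10 m/s cruise, 2 s cruise, a turn at
#' 15 deg/s^2 angular acceleration, 3 s cruise and 1 s deceleration, with
#' trial turn angles of 60 deg left, 90 deg right, 90 deg right, 60 deg left
#' (see [default_trial_plan()]).
#'
#' @param turn_angle Signed turn angle in degrees; positive is rightward
#'   (clockwise), negative leftward. `0` is allowed for pure kinematics but
#'   not for strategy-quadrant derivation.
#' @param lin_accel Linear acceleration of the first phase, m/s^2 (> 0).
#' @param cruise_speed Translational cruise speed, m/s (> 0). Must equal
#'   `lin_accel * t_accel1`: the acceleration phase ends at cruise speed.
#' @param ang_accel Angular acceleration of each half of the turn,
#'   deg/s^2 (> 0).
#' @param t_accel1,t_const1,t_const2,t_decel2 Phase durations in seconds
#'   (>= 0): linear acceleration, first cruise, second cruise, final linear
#'   deceleration.
#' @return An object of class `"path_spec"`.
#' @examples
#' spec <- path_spec(-60)
#' turn_duration(spec$turn_angle)
#' end_pose(spec)
#' @export
path_spec <- function(turn_angle, lin_accel = 10, cruise_speed = 10,
                      ang_accel = 15, t_accel1 = 1, t_const1 = 2,
                      t_const2 = 3, t_decel2 = 1) {
  for (nm in c("turn_angle", "lin_accel", "cruise_speed", "ang_accel",
               "t_accel1", "t_const1", "t_const2", "t_decel2")) {
    check_scalar_number(get(nm), nm)
  }
  if (lin_accel <= 0 || cruise_speed <= 0 || ang_accel <= 0) {
    po_stop("lin_accel, cruise_speed and ang_accel must all be positive",
            "po_invalid_parameter")
  }
  if (t_accel1 < 0 || t_const1 < 0 || t_const2 < 0 || t_decel2 < 0) {
    po_stop("phase durations must be non-negative", "po_invalid_parameter")
  }
  if (abs(cruise_speed - lin_accel * t_accel1) > 1e-8) {
    po_stop("cruise_speed must equal lin_accel * t_accel1 (the acceleration phase ends at cruise speed)",
            "po_invalid_parameter")
  }
  if (abs(turn_angle) > 180) {
    po_stop("|turn_angle| must be at most 180 degrees", "po_invalid_parameter")
  }
  structure(list(turn_angle = turn_angle, lin_accel = lin_accel,
                 cruise_speed = cruise_speed, ang_accel = ang_accel,
                 t_accel1 = t_accel1, t_const1 = t_const1,
                 t_const2 = t_const2, t_decel2 = t_decel2),
            class = "path_spec")
}

#' @export
print.path_spec <- function(x, ...) {
  cat(sprintf(
    "<path_spec> turn %+g deg | accel %gs @ %g m/s^2 -> %g m/s | cruise %gs | turn %.4gs @ %g deg/s^2 | cruise %gs | decel %gs\n",
    x$turn_angle, x$t_accel1, x$lin_accel, x$cruise_speed, x$t_const1,
    turn_duration(x$turn_angle, x$ang_accel), x$ang_accel, x$t_const2,
    x$t_decel2))
  invisible(x)
}

#' Default trial plan of signed turn angles
#'
#' The four-trial sequence used by the study design this package models:
#' 60 deg left, 90 deg right, 90 deg right, 60 deg left.
#'
#' @return A numeric vector of four signed turn angles in degrees.
#' @export
default_trial_plan <- function() c(-60, 90, 90, -60)

#' Duration of a symmetric accelerate/decelerate turn
#'
#' The curve is divided into an angular accelerating half and a decelerating
#' half with constant angular acceleration `ang_accel`, giving a triangular
#' angular-velocity profile. Covering `|turn_angle|` degrees then takes
#' `T = 2 * sqrt(|turn_angle| / ang_accel)` seconds: 4 s for 60 deg at
#' 15 deg/s^2, and 4.899 s for 90 deg.
#'
#' @param turn_angle Signed turn angle in degrees.
#' @param ang_accel Angular acceleration in deg/s^2 (> 0).
#' @return Turn duration in seconds.
#' @export
turn_duration <- function(turn_angle, ang_accel = 15) {
  check_scalar_number(ang_accel, "ang_accel")
  if (ang_accel <= 0) {
    po_stop("ang_accel must be positive", "po_invalid_parameter")
  }
  2 * sqrt(abs(turn_angle) / ang_accel)
}

phase_times <- function(spec) {
  tt <- turn_duration(spec$turn_angle, spec$ang_accel)
  b <- cumsum(c(spec$t_accel1, spec$t_const1, tt, spec$t_const2, spec$t_decel2))
  list(turn = tt, end_accel = b[1], start_turn = b[2], end_turn = b[3],
       start_decel = b[4], total = b[5])
}

# Vectorized translational speed at time t (m/s).
speed_at <- function(spec, t) {
  p <- phase_times(spec)
  v <- spec$cruise_speed
  out <- rep(v, length(t))
  acc <- t < p$end_accel
  out[acc] <- spec$lin_accel * t[acc]
  if (spec$t_decel2 > 0) {
    dec <- t > p$start_decel
    out[dec] <- pmax(0, v - (v / spec$t_decel2) * (t[dec] - p$start_decel))
  }
  out
}

# Vectorized heading at time t (degrees, signed; triangular angular-velocity
# profile during the turn).
heading_at <- function(spec, t) {
  p <- phase_times(spec)
  s <- sign(spec$turn_angle)
  th <- abs(spec$turn_angle)
  a <- spec$ang_accel
  out <- rep(spec$turn_angle, length(t))
  out[t <= p$start_turn] <- 0
  if (p$turn > 0) {
    tb <- t - p$start_turn
    h1 <- tb > 0 & tb <= p$turn / 2
    h2 <- tb > p$turn / 2 & tb < p$turn
    out[h1] <- s * 0.5 * a * tb[h1]^2
    out[h2] <- s * (th - 0.5 * a * (p$turn - tb[h2])^2)
  }
  out
}

#' Simulate the outbound trajectory
#'
#' Piecewise integration of the five stimulus phases: linear acceleration,
#' cruise, curve (triangular angular-velocity profile at constant
#' translational speed), cruise, and linear deceleration. Positions are
#' obtained by trapezoidal integration of the exact velocity and heading
#' profiles on a regular time grid.
#'
#' @param spec A [path_spec()].
#' @param dt Integration time step in seconds (> 0). The default 1 ms keeps
#'   the integrated path length within 0.1% of the analytic phase distances.
#' @return A data frame with columns `time` (s), `x` (m, rightward), `z`
#'   (m, initial-forward) and `heading` (degrees).
#' @seealso [end_pose()] for the closed-form endpoint.
#' @export
simulate_trajectory <- function(spec, dt = 1e-3) {
  stopifnot(inherits(spec, "path_spec"))
  check_scalar_number(dt, "dt")
  if (dt <= 0) po_stop("dt must be positive", "po_invalid_parameter")
  p <- phase_times(spec)
  times <- seq(0, p$total, by = dt)
  if (times[length(times)] < p$total) times <- c(times, p$total)
  v <- speed_at(spec, times)
  h <- heading_at(spec, times)
  hr <- deg2rad(h)
  vx <- v * sin(hr)
  vz <- v * cos(hr)
  dtv <- diff(times)
  x <- c(0, cumsum((vx[-1] + vx[-length(vx)]) / 2 * dtv))
  z <- c(0, cumsum((vz[-1] + vz[-length(vz)]) / 2 * dtv))
  data.frame(time = times, x = x, z = z, heading = norm_angle(h))
}

#' Closed-form end pose of a trajectory
#'
#' The straight phases are evaluated analytically; the curve displacement is
#' obtained by high-accuracy quadrature of the heading profile, so the result
#' matches [simulate_trajectory()] in the limit of a vanishing time step.
#'
#' @param spec A [path_spec()].
#' @return A [pose()]: the endpoint position and final heading.
#' @export
end_pose <- function(spec) {
  stopifnot(inherits(spec, "path_spec"))
  v <- spec$cruise_speed
  p <- phase_times(spec)
  # first straight: accelerate + cruise along +z
  d1 <- 0.5 * spec$lin_accel * spec$t_accel1^2 + v * spec$t_const1
  x <- 0
  z <- d1
  if (p$turn > 0) {
    s <- sign(spec$turn_angle)
    th <- abs(spec$turn_angle)
    a <- spec$ang_accel
    phi <- function(tb) {
      ifelse(tb <= p$turn / 2,
             s * 0.5 * a * tb^2,
             s * (th - 0.5 * a * (p$turn - tb)^2))
    }
    half <- p$turn / 2
    ix <- function(lo, hi) {
      stats::integrate(function(u) v * sin(deg2rad(phi(u))), lo, hi,
                       rel.tol = 1e-12, abs.tol = 1e-12)$value
    }
    iz <- function(lo, hi) {
      stats::integrate(function(u) v * cos(deg2rad(phi(u))), lo, hi,
                       rel.tol = 1e-12, abs.tol = 1e-12)$value
    }
    x <- x + ix(0, half) + ix(half, p$turn)
    z <- z + iz(0, half) + iz(half, p$turn)
  }
  # second straight: cruise + decelerate along the final heading
  d2 <- v * spec$t_const2 + 0.5 * v * spec$t_decel2
  hr <- deg2rad(spec$turn_angle)
  pose(x + d2 * sin(hr), z + d2 * cos(hr), spec$turn_angle)
}

#' Construct a pose
#'
#' A pose is a position on the ground plane plus a heading: `x` is rightward
#' displacement (m), `z` displacement along the initial facing direction (m),
#' and `heading` is measured from the initial facing direction in degrees,
#' positive clockwise, normalized to (-180, 180].
#'
#' @param x,z Position in metres.
#' @param heading Heading in degrees.
#' @return An object of class `"pose"`.
#' @export
pose <- function(x, z, heading = 0) {
  check_scalar_number(x, "x"); check_scalar_number(z, "z")
  check_scalar_number(heading, "heading")
  structure(list(x = x, z = z, heading = norm_angle(heading)), class = "pose")
}

#' @export
print.pose <- function(x, ...) {
  cat(sprintf("<pose> x = %.3f m, z = %.3f m, heading = %.3f deg\n",
              x$x, x$z, x$heading))
  invisible(x)
}

# Signed egocentric bearing, in degrees (-180, 180], of world vector
# (vx, vz) in a frame facing reference_heading; positive = rightward.
bearing_of_vector <- function(vx, vz, reference_heading) {
  if (sqrt(vx^2 + vz^2) < 1e-12) {
    po_stop("zero-length vector has no bearing", "po_degenerate_geometry")
  }
  h <- deg2rad(reference_heading)
  fwd <- vx * sin(h) + vz * cos(h)
  rgt <- vx * cos(h) - vz * sin(h)
  norm_angle(atan2(rgt, fwd) * 180 / pi)
}

#' Egocentric bearing of the origin from an end pose
#'
#' The homing direction: the signed bearing in (-180, 180] of the vector
#' from the end position back to the origin, expressed in a frame facing
#' `reference_heading`. Positive bearings are to the right; |bearing| > 90
#' means the origin is behind.
#'
#' @param end A [pose()]; must not sit on the origin.
#' @param reference_heading Heading of the reference frame in degrees.
#' @return Bearing in degrees.
#' @examples
#' homing_bearing(pose(0, 10), 0)    # directly behind: 180
#' homing_bearing(pose(-10, 0), 0)   # directly right:   +90
#' @export
homing_bearing <- function(end, reference_heading) {
  stopifnot(inherits(end, "pose"))
  check_scalar_number(reference_heading, "reference_heading")
  bearing_of_vector(-end$x, -end$z, reference_heading)
}

# Quadrant code of a bearing; bearings on a boundary are refused rather than
# tie-broken (the experiment's turn angles never produce them).
quadrant_of_bearing <- function(bearing, tol = 1e-9) {
  if (min(abs(norm_angle(bearing - c(0, 90, -90, 180)))) < tol) {
    po_stop(sprintf("bearing %.6g deg lies on a quadrant boundary", bearing),
            "po_degenerate_geometry")
  }
  paste0(if (abs(bearing) < 90) "F" else "B",
         if (bearing < 0) "L" else "R")
}

#' Quadrant predicted by a response strategy
#'
#' Each hypothesised strategy implies a reference frame in which the
#' homing direction is expressed, and hence a unique answer quadrant for a
#' given outbound path:
#'
#' * `turner`: homing bearing in the frame of the **final** heading (the
#'   simulated turn was updated);
#' * `non-turner`: homing bearing in the frame of the **initial** heading
#'   (the turn was not updated);
#' * `non-mover`: bearing of the vector from origin to endpoint in the
#'   initial frame (pointing "where I went" rather than "where I came from");
#' * `spinner`: homing bearing in the final frame rotated by 180 degrees
#'   (as if turning to face the path before pointing).
#'
#' For any turn magnitude in (0, 135) degrees under the default path the
#' four strategies map onto four distinct quadrants, and negating the turn
#' angle mirrors every quadrant left-right.
#'
#' @param strategy One of [strategies()].
#' @param spec A [path_spec()] with `|turn_angle|` in (0, 135).
#' @return A quadrant code (see [quadrants()]).
#' @examples
#' predicted_quadrant("turner", path_spec(-60))     # "BL"
#' predicted_quadrant("non-mover", path_spec(-60))  # "FL"
#' @export
predicted_quadrant <- function(strategy, spec) {
  strategy <- match.arg(strategy, strategies())
  stopifnot(inherits(spec, "path_spec"))
  if (abs(spec$turn_angle) <= 0 || abs(spec$turn_angle) >= 135) {
    po_stop("strategy-quadrant derivation requires |turn_angle| in (0, 135) degrees",
            "po_invalid_parameter")
  }
  e <- end_pose(spec)
  b <- switch(strategy,
    "turner" = homing_bearing(e, e$heading),
    "non-turner" = homing_bearing(e, 0),
    "non-mover" = bearing_of_vector(e$x, e$z, 0),
    "spinner" = homing_bearing(e, e$heading + 180))
  quadrant_of_bearing(b)
}

#' Map every strategy to its predicted quadrant
#'
#' @param spec A [path_spec()], or a bare signed turn angle in degrees (the
#'   remaining path parameters then take their defaults).
#' @return A named character vector: strategy -> quadrant code. The map is a
#'   bijection for any turn magnitude in (0, 135) degrees.
#' @export
strategy_quadrant_map <- function(spec) {
  if (is.numeric(spec)) spec <- path_spec(spec)
  out <- vapply(strategies(), predicted_quadrant, character(1), spec = spec)
  if (anyDuplicated(out)) {
    po_stop("strategy-quadrant map is not a bijection for this path",
            "po_degenerate_geometry")
  }
  out
}

#' Read or write a path specification
#'
#' Path specifications are serialized as JSON or YAML (chosen by file
#' extension) with the field names of [path_spec()].
#'
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `read_path_spec()` returns a [path_spec()];
#'   `write_path_spec()` returns `path` invisibly.
#' @export
read_path_spec <- function(path) {
  fields <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  do.call(path_spec, fields)
}

#' @rdname read_path_spec
#' @param spec A [path_spec()].
#' @export
write_path_spec <- function(spec, path) {
  stopifnot(inherits(spec, "path_spec"))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(unclass(spec), path)
  }
  invisible(path)
}

#' Write a simulated trajectory as CSV
#'
#' Writes the `time,x,z,heading` pose series of [simulate_trajectory()] as a
#' UTF-8, comma-separated file with a header row.
#'
#' @param trajectory Data frame from [simulate_trajectory()].
#' @param path Output file path.
#' @export
write_trajectory_csv <- function(trajectory, path) {
  stopifnot(all(c("time", "x", "z", "heading") %in% names(trajectory)))
  utils::write.csv(trajectory[, c("time", "x", "z", "heading")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}
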
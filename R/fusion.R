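# Madgwick gradient-descent orientation estimation (IMU variant:
# accelerometer + gyroscope; the phone's magnetometer is recorded but unused
# because indoor magnetic disturbance makes yaw unreliable, and only the
# vertical acceleration is consumed downstream).
#
# State is the unit quaternion q mapping sensor coordinates to the world
# frame (z up). Each step integrates the gyroscope quaternion rate and
# subtracts beta times the normalised gradient of the accelerometer
# objective f(q) = R(q)^T e_z - a/||a||, which pulls the estimated gravity
# direction towards the measured one and so compensates long-term gyro
# integration drift.

#' Fusion configuration
#'
#' @param beta algorithm gain, rad/s (>= 0). `beta = 0` reduces the filter
#'   to pure gyroscope integration. Default 0.1 rad/s (the method's
#'   published default).
#' @param q0 initial orientation (unit quaternion) or `NULL` to initialise
#'   tilt from the first accelerometer sample (zero yaw).
#' @param gravity gravitational acceleration, m/s^2.
#' @return object of class `fusion_config`.
#' @export
fusion_config <- function(beta = 0.1, q0 = NULL, gravity = 9.80665) {
  if (beta < 0) stop("beta must be >= 0")
  if (!is.null(q0)) {
    if (abs(sqrt(sum(q0^2)) - 1) > 1e-6) stop("q0 must be unit norm")
    q0 <- quat_normalize(q0)
  }
  structure(list(beta = beta, q0 = q0, gravity = gravity),
            class = "fusion_config")
}

#' One Madgwick filter update
#'
#' @param q current orientation estimate (unit quaternion, sensor-to-world).
#' @param gyro angular rate, rad/s, sensor frame.
#' @param accel specific force, m/s^2, sensor frame; the correction is
#'   skipped when its norm is (numerically) zero.
#' @param dt time step, seconds (> 0).
#' @param cfg a [fusion_config()].
#' @return updated unit quaternion.
#' @export
madgwick_step <- function(q, gyro, accel, dt, cfg = fusion_config()) {
  if (abs(sqrt(sum(q^2)) - 1) > 1e-6)
    stop("state error: q must be a unit quaternion")
  if (dt <= 0) stop("dt must be positive")
  qdot <- 0.5 * quat_multiply(q, c(0, gyro))
  an <- sqrt(sum(accel^2))
  if (cfg$beta > 0 && an > 1e-9) {
    a <- accel / an
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    # f = R(q)^T e_z - a  (predicted minus measured gravity direction)
    f1 <- 2 * (x * z - w * y) - a[1]
    f2 <- 2 * (w * x + y * z) - a[2]
    f3 <- w^2 - x^2 - y^2 + z^2 - a[3]
    g <- c(-2 * y * f1 + 2 * x * f2 + 2 * w * f3,
            2 * z * f1 + 2 * w * f2 - 2 * x * f3,
           -2 * w * f1 + 2 * z * f2 - 2 * y * f3,
            2 * x * f1 + 2 * y * f2 + 2 * z * f3)
    gn <- sqrt(sum(g^2))
    if (gn > 1e-12) qdot <- qdot - cfg$beta * g / gn
  }
  quat_normalize(q + qdot * dt)
}

# Tilt-only quaternion whose R^T maps world e_z onto the measured gravity
# direction (zero yaw): rotation about the axis e_z x a by the tilt angle.
tilt_from_accel <- function(accel) {
  an <- sqrt(sum(accel^2))
  if (an < 1e-9) return(c(1, 0, 0, 0))
  a <- accel / an
  # rotate the measured gravity direction onto world up: axis a x e_z,
  # angle acos(a . e_z)
  axis <- c(a[2], -a[1], 0)
  na <- sqrt(sum(axis^2))
  ang <- acos(max(-1, min(1, a[3])))
  if (na < 1e-12) {
    if (a[3] > 0) return(c(1, 0, 0, 0))
    return(c(0, 1, 0, 0))          # upside down: 180 deg about x
  }
  quat_from_axis_angle(axis / na, ang)
}

#' Estimate an orientation stream by Madgwick fusion
#'
#' Accelerometer and gyroscope streams are resampled onto `grid` by linear
#' interpolation, then folded through [madgwick_step()]. The first output
#' sample is the initial orientation advanced by one step.
#'
#' @param rec a [phone_recording()] or [imu_recording()].
#' @param cfg a [fusion_config()].
#' @param grid uniform time grid (seconds); defaults to a 100 Hz grid over
#'   the common span of the two sensor streams.
#' @param fs grid rate used when `grid` is omitted.
#' @return a [quaternion_series()] on `grid` (sensor-to-world).
#' @export
estimate_orientation <- function(rec, cfg = fusion_config(), grid = NULL,
                                 fs = 100) {
  if (inherits(rec, "phone_recording")) {
    acc_s <- rec$accelerometer; gyr_s <- rec$gyroscope
  } else if (inherits(rec, "imu_recording")) {
    acc_s <- list(time = series_time(rec$accelerometer),
                  values = rec$accelerometer$values)
    gyr_s <- list(time = series_time(rec$gyroscope),
                  values = rec$gyroscope$values)
  } else stop("rec must be a phone_recording or imu_recording")
  if (is.null(grid)) grid <- common_grid(fs, acc_s, gyr_s)
  acc <- resample_linear(acc_s$time, acc_s$values, grid)$values
  gyr <- resample_linear(gyr_s$time, gyr_s$values, grid)$values
  q <- cfg$q0 %||% tilt_from_accel(acc[1, ])
  out <- matrix(NA_real_, length(grid), 4L)
  dt <- c(diff(grid)[1], diff(grid))
  for (i in seq_along(grid)) {
    q <- madgwick_step(q, gyr[i, ], acc[i, ], dt[i], cfg)
    out[i, ] <- q
  }
  quaternion_series(grid, out)
}

#' Global vertical acceleration
#'
#' Rotates the measured specific force into the world frame and subtracts
#' gravity: `a_vert(t) = [R(q_t) accel(t)]_z - g`. A stationary sensor with
#' a correct orientation estimate gives values near zero.
#'
#' @param rec recording providing the accelerometer stream.
#' @param orientation a [quaternion_series()] on the same grid.
#' @param cfg a [fusion_config()] (supplies `gravity`).
#' @return a [uniform_series()] of vertical acceleration, m/s^2.
#' @export
global_vertical_acceleration <- function(rec, orientation,
                                         cfg = fusion_config()) {
  grid <- orientation$timestamps
  if (inherits(rec, "phone_recording")) {
    acc_t <- rec$accelerometer$time; acc_v <- rec$accelerometer$values
  } else {
    acc_t <- series_time(rec$accelerometer); acc_v <- rec$accelerometer$values
  }
  if (min(grid) < min(acc_t) - 1e-9 || max(grid) > max(acc_t) + 1e-9)
    stop("alignment error: orientation grid outside accelerometer span")
  acc <- resample_linear(acc_t, acc_v, grid)$values
  world <- quat_rotate(orientation$quaternions, acc)
  fs <- 1 / stats::median(diff(grid))
  uniform_series(world[, 3] - cfg$gravity, fs = fs, t0 = grid[1],
                 label = "vertical acceleration")
}
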
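# Recording containers shared by every pipeline: regularly sampled series,
# orientation streams, marker sets, and the two wearable recording types.
# All internal units are SI (m, s, rad, m/s^2); degrees appear only at
# reporting boundaries.

#' Regularly sampled scalar or vector series
#'
#' The common currency of all pipelines: samples on the uniform grid
#' `t0 + (0:(n-1))/fs`.
#'
#' @param values numeric vector (scalar samples) or N x k matrix (fixed-width
#'   vector samples, one sample per row).
#' @param fs sampling frequency, Hz (> 0).
#' @param t0 time of the first sample, seconds.
#' @param label free-text description.
#' @return object of class `uniform_series` with fields `t0`, `fs`, `values`
#'   (always a matrix), `label`.
#' @export
uniform_series <- function(values, fs, t0 = 0, label = "") {
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("fs must be a single positive number")
  if (is.null(dim(values))) values <- matrix(as.numeric(values), ncol = 1L)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) < 1L) stop("a series needs at least one sample")
  structure(list(t0 = as.numeric(t0), fs = fs, values = values,
                 label = as.character(label)),
            class = "uniform_series")
}

#' @export
print.uniform_series <- function(x, ...) {
  cat(sprintf("<uniform_series> %s: %d samples x %d, fs %g Hz, t0 %g s\n",
              if (nzchar(x$label)) x$label else "(unlabelled)",
              nrow(x$values), ncol(x$values), x$fs, x$t0))
  invisible(x)
}

#' Time stamps of a uniform series
#' @param x a `uniform_series`.
#' @return numeric vector of sample times, seconds.
#' @export
series_time <- function(x) x$t0 + (seq_len(nrow(x$values)) - 1L) / x$fs

#' Irregularly time-stamped orientation stream
#'
#' @param timestamps strictly increasing sample times, seconds.
#' @param quaternions N x 4 matrix of unit quaternions (w, x, y, z),
#'   frame rotations sensor-to-world.
#' @return object of class `quaternion_series`.
#' @export
quaternion_series <- function(timestamps, quaternions) {
  quaternions <- as_quat_matrix(quaternions)
  if (length(timestamps) != nrow(quaternions))
    stop("timestamps and quaternions disagree in length")
  if (length(timestamps) > 1L && any(diff(timestamps) <= 0))
    stop("timestamps must be strictly increasing")
  norms <- sqrt(rowSums(quaternions^2))
  if (any(abs(norms - 1) > 1e-9))
    stop("quaternions must be unit norm (tolerance 1e-9)")
  structure(list(timestamps = as.numeric(timestamps),
                 quaternions = quaternions),
            class = "quaternion_series")
}

#' @export
print.quaternion_series <- function(x, ...) {
  cat(sprintf("<quaternion_series> %d samples spanning %.3f s\n",
              length(x$timestamps), diff(range(x$timestamps))))
  invisible(x)
}

#' Marker trajectory set
#'
#' @param trajectories named list of `uniform_series`, each N x 3 positions
#'   in meters; all sharing `t0` and `fs`.
#' @param gaps optional N x n_marker logical matrix flagging occluded samples.
#' @return object of class `marker_set`.
#' @export
marker_set <- function(trajectories, gaps = NULL) {
  if (length(trajectories) == 0L || is.null(names(trajectories)))
    stop("trajectories must be a non-empty named list")
  fs <- vapply(trajectories, function(s) s$fs, numeric(1))
  t0 <- vapply(trajectories, function(s) s$t0, numeric(1))
  if (any(fs != fs[1]) || any(t0 != t0[1]))
    stop("all marker trajectories must share t0 and fs")
  n <- vapply(trajectories, function(s) nrow(s$values), integer(1))
  if (any(n != n[1])) stop("all marker trajectories must share length")
  if (is.null(gaps)) gaps <- matrix(FALSE, n[1], length(trajectories),
                                    dimnames = list(NULL, names(trajectories)))
  for (i in seq_along(trajectories)) {
    v <- trajectories[[i]]$values
    if (ncol(v) != 3L) stop("marker trajectories must be N x 3")
    ok <- !gaps[, i]
    if (any(!is.finite(v[ok, ]))) stop("non-finite position outside a gap")
  }
  structure(list(trajectories = trajectories, gaps = gaps,
                 fs = unname(fs[1]), t0 = unname(t0[1]), n = unname(n[1])),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("<marker_set> %d markers x %d samples, fs %g Hz\n",
              length(x$trajectories), x$n, x$fs))
  invisible(x)
}

#' Marker positions at one sample
#' @param ms a `marker_set`.
#' @param i sample index.
#' @return named n_marker x 3 matrix (occluded markers as NA rows).
#' @export
marker_frame <- function(ms, i) {
  out <- t(vapply(ms$trajectories, function(s) s$values[i, ], numeric(3)))
  out[ms$gaps[i, ], ] <- NA_real_
  colnames(out) <- c("x", "y", "z")
  out
}

#' Inertial measurement unit recording
#'
#' @param sensor_id segment name the unit is mounted on.
#' @param accelerometer `uniform_series`, N x 3, m/s^2, sensor frame.
#' @param gyroscope `uniform_series`, N x 3, rad/s, sensor frame.
#' @param orientation optional `quaternion_series` (sensor to world).
#' @return object of class `imu_recording`.
#' @export
imu_recording <- function(sensor_id, accelerometer, gyroscope,
                          orientation = NULL) {
  stopifnot(inherits(accelerometer, "uniform_series"),
            inherits(gyroscope, "uniform_series"))
  if (accelerometer$fs != gyroscope$fs)
    stop("accelerometer and gyroscope must share the sampling rate")
  if (!is.null(orientation) && !inherits(orientation, "quaternion_series"))
    stop("orientation must be a quaternion_series or NULL")
  structure(list(sensor_id = as.character(sensor_id),
                 accelerometer = accelerometer, gyroscope = gyroscope,
                 orientation = orientation),
            class = "imu_recording")
}

#' Pocket smartphone recording
#'
#' Each stream keeps its own (strictly increasing) timestamp vector, as
#' delivered by phone sensor APIs.
#'
#' @param side `"left"` or `"right"` trouser pocket.
#' @param accelerometer,gyroscope lists with fields `time` (s) and `values`
#'   (N x 3; m/s^2 and rad/s, device frame).
#' @param magnetometer optional stream in the same layout (recorded but not
#'   used by the shipped fusion).
#' @param orientation optional vendor `quaternion_series`.
#' @return object of class `phone_recording`.
#' @export
phone_recording <- function(side, accelerometer, gyroscope,
                            magnetometer = NULL, orientation = NULL) {
  side <- match.arg(side, c("left", "right"))
  check_stream <- function(s, what) {
    if (!is.list(s) || is.null(s$time) || is.null(s$values))
      stop(sprintf("%s stream needs $time and $values", what))
    if (is.null(dim(s$values))) s$values <- matrix(s$values, ncol = 3L)
    if (length(s$time) != nrow(s$values))
      stop(sprintf("%s stream length mismatch", what))
    if (length(s$time) > 1L && any(diff(s$time) <= 0))
      stop(sprintf("%s timestamps must be strictly increasing", what))
    s
  }
  accelerometer <- check_stream(accelerometer, "accelerometer")
  gyroscope <- check_stream(gyroscope, "gyroscope")
  if (!is.null(magnetometer)) magnetometer <- check_stream(magnetometer, "magnetometer")
  structure(list(side = side, accelerometer = accelerometer,
                 gyroscope = gyroscope, magnetometer = magnetometer,
                 orientation = orientation),
            class = "phone_recording")
}

# ---------------------------------------------------------------------------
# Delimited-text recording I/O.
#
# Marker file: TSV, header `time` then `<label>_x  <label>_y  <label>_z`
#   triplets, positions in meters, occlusions as empty fields.
# IMU file:    CSV, header time,acc_x,acc_y,acc_z,gyr_x,gyr_y,gyr_z[,qw,qx,qy,qz]
# Phone file:  CSV, long format time,sensor,x,y,z with sensor in {acc,gyr,mag}.

#' Read a recording file
#'
#' @param path file path.
#' @param schema one of `"marker"`, `"imu"`, `"phone"`.
#' @param side pocket side for phone files.
#' @param sensor_id segment name for IMU files (defaults to the file stem).
#' @return a `marker_set`, `imu_recording` or `phone_recording`.
#' @export
read_recording <- function(path, schema = c("marker", "imu", "phone"),
                           side = "left", sensor_id = NULL) {
  schema <- match.arg(schema)
  if (!file.exists(path)) stop("file not found: ", path)
  switch(schema,
         marker = read_marker_file(path),
         imu = read_imu_file(path, sensor_id %||% sub("\\.[^.]*$", "", basename(path))),
         phone = read_phone_file(path, side))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_time_column <- function(df, path) {
  if (!"time" %in% names(df))
    stop("schema error in ", path, ": missing column 'time'")
  tm <- df$time
  if (any(!is.finite(tm)) || (length(tm) > 1L && any(diff(tm) <= 0)))
    stop("data error in ", path, ": timestamps must be strictly increasing")
  tm
}

read_marker_file <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  tm <- check_time_column(df, path)
  cols <- setdiff(names(df), "time")
  labs <- unique(sub("_[xyz]$", "", cols))
  fs <- infer_fs(tm, path)
  trajs <- list(); gaps <- NULL
  for (lab in labs) {
    need <- paste0(lab, "_", c("x", "y", "z"))
    if (!all(need %in% cols))
      stop("schema error in ", path, ": missing column ",
           need[!need %in% cols][1])
    v <- as.matrix(df[, need])
    g <- apply(is.na(v), 1L, any)
    v[g, ] <- NA_real_
    trajs[[lab]] <- uniform_series(v, fs = fs, t0 = tm[1], label = lab)
    gaps <- cbind(gaps, g)
  }
  colnames(gaps) <- labs
  marker_set(trajs, gaps = gaps)
}

infer_fs <- function(tm, path) {
  if (length(tm) < 2L) return(1)
  dt <- diff(tm)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("data error in ", path, ": sampling grid is not uniform")
  1 / stats::median(dt)
}

read_imu_file <- function(path, sensor_id) {
  df <- utils::read.csv(path, check.names = FALSE)
  tm <- check_time_column(df, path)
  need <- c("acc_x", "acc_y", "acc_z", "gyr_x", "gyr_y", "gyr_z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error in ", path, ": missing column ", miss[1])
  fs <- infer_fs(tm, path)
  acc <- uniform_series(as.matrix(df[, need[1:3]]), fs, tm[1], "accelerometer")
  gyr <- uniform_series(as.matrix(df[, need[4:6]]), fs, tm[1], "gyroscope")
  ori <- NULL
  qcols <- c("qw", "qx", "qy", "qz")
  if (all(qcols %in% names(df)))
    ori <- quaternion_series(tm, quat_normalize(as.matrix(df[, qcols])))
  imu_recording(sensor_id, acc, gyr, ori)
}

read_phone_file <- function(path, side) {
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("time", "sensor", "x", "y", "z")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("schema error in ", path, ": missing column ", miss[1])
  pull <- function(tag) {
    sub <- df[df$sensor == tag, , drop = FALSE]
    if (nrow(sub) == 0L) return(NULL)
    if (any(diff(sub$time) <= 0))
      stop("data error in ", path, ": non-monotone '", tag, "' timestamps")
    list(time = sub$time, values = as.matrix(sub[, c("x", "y", "z")]))
  }
  acc <- pull("acc"); gyr <- pull("gyr")
  if (is.null(acc) || is.null(gyr))
    stop("schema error in ", path, ": phone file needs acc and gyr rows")
  phone_recording(side, acc, gyr, magnetometer = pull("mag"))
}

#' Write a recording to its delimited-text format
#'
#' Inverse of [read_recording()]; round-trips numeric content.
#'
#' @param rec a `marker_set`, `imu_recording` or `phone_recording`.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  if (inherits(rec, "marker_set")) {
    tm <- rec$t0 + (seq_len(rec$n) - 1L) / rec$fs
    df <- data.frame(time = tm, check.names = FALSE)
    for (lab in names(rec$trajectories)) {
      v <- rec$trajectories[[lab]]$values
      v[rec$gaps[, lab], ] <- NA_real_
      df[[paste0(lab, "_x")]] <- v[, 1]
      df[[paste0(lab, "_y")]] <- v[, 2]
      df[[paste0(lab, "_z")]] <- v[, 3]
    }
    utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  } else if (inherits(rec, "imu_recording")) {
    tm <- series_time(rec$accelerometer)
    df <- data.frame(time = tm,
                     acc_x = rec$accelerometer$values[, 1],
                     acc_y = rec$accelerometer$values[, 2],
                     acc_z = rec$accelerometer$values[, 3],
                     gyr_x = rec$gyroscope$values[, 1],
                     gyr_y = rec$gyroscope$values[, 2],
                     gyr_z = rec$gyroscope$values[, 3])
    if (!is.null(rec$orientation)) {
      q <- rec$orientation$quaternions
      df$qw <- q[, 1]; df$qx <- q[, 2]; df$qy <- q[, 3]; df$qz <- q[, 4]
    }
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else if (inherits(rec, "phone_recording")) {
    one <- function(tag, s) if (is.null(s)) NULL else
      data.frame(time = s$time, sensor = tag,
                 x = s$values[, 1], y = s$values[, 2], z = s$values[, 3])
    df <- rbind(one("acc", rec$accelerometer), one("gyr", rec$gyroscope),
                one("mag", rec$magnetometer))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else stop("unsupported recording type")
  invisible(path)
}

#' Linearly fill marker occlusion gaps
#'
#' Provided as an explicit helper; gaps are never filled silently by any
#' pipeline stage.
#'
#' @param ms a `marker_set`.
#' @param max_gap longest gap (in samples) that may be bridged.
#' @return a `marker_set` with bridgeable gaps interpolated and unflagged.
#' @export
fill_marker_gaps <- function(ms, max_gap = 10L) {
  for (lab in names(ms$trajectories)) {
    g <- ms$gaps[, lab]
    if (!any(g)) next
    v <- ms$trajectories[[lab]]$values
    runs <- rle(g)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values)) {
      a <- idx_start[r] - 1L; b <- idx_end[r] + 1L
      if (a < 1L || b > nrow(v) || runs$lengths[r] > max_gap) next
      for (k in 1:3)
        v[(a + 1L):(b - 1L), k] <- seq(v[a, k], v[b, k],
                                       length.out = b - a + 1L)[2:(b - a)]
      g[(a + 1L):(b - 1L)] <- FALSE
    }
    ms$trajectories[[lab]]$values <- v
    ms$gaps[, lab] <- g
  }
  ms
}
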
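# Resampling/synchronisation: per-sensor streams with independent clocks are
# brought onto one uniform grid by linear interpolation (scalar/vector data)
# and spherical linear interpolation (orientation data).

#' Linear resampling onto a uniform grid
#'
#' @param time source sample times, strictly increasing, seconds.
#' @param values numeric vector or N x k matrix of source samples.
#' @param grid target times; must lie inside `[min(time), max(time)]`
#'   (no extrapolation).
#' @param fs,t0 optional: describe `grid` when it is uniform so the result
#'   carries exact grid metadata; when omitted they are inferred from `grid`.
#' @param label label for the returned series.
#' @return a [uniform_series()] sampled on `grid`.
#' @export
resample_linear <- function(time, values, grid, fs = NULL, t0 = NULL,
                            label = "") {
  if (any(diff(time) <= 0)) stop("source timestamps must be strictly increasing")
  if (min(grid) < min(time) - 1e-12 || max(grid) > max(time) + 1e-12)
    stop("range error: target grid extends beyond the source time span")
  if (is.null(dim(values))) values <- matrix(values, ncol = 1L)
  out <- vapply(seq_len(ncol(values)), function(k)
    stats::approx(time, values[, k], xout = grid, rule = 1,
                  ties = "ordered")$y,
    numeric(length(grid)))
  if (is.null(dim(out))) out <- matrix(out, nrow = length(grid))
  if (is.null(fs)) {
    fs <- if (length(grid) > 1L) 1 / stats::median(diff(grid)) else 1
    t0 <- grid[1]
  }
  uniform_series(out, fs = fs, t0 = t0 %||% grid[1], label = label)
}

#' Slerp resampling of an orientation stream
#'
#' Geodesic (great-circle) interpolation between bracketing quaternions,
#' exact at coincident times; antipodal representations are resolved to the
#' short arc.
#'
#' @param qs a [quaternion_series()].
#' @param grid target times inside the source span.
#' @return a [quaternion_series()] sampled at `grid`.
#' @export
resample_slerp <- function(qs, grid) {
  tm <- qs$timestamps
  if (min(grid) < tm[1] - 1e-12 || max(grid) > tm[length(tm)] + 1e-12)
    stop("range error: target grid extends beyond the source time span")
  grid <- pmin(pmax(grid, tm[1]), tm[length(tm)])
  idx <- findInterval(grid, tm, rightmost.closed = TRUE)
  idx <- pmin(pmax(idx, 1L), length(tm) - 1L)
  u <- (grid - tm[idx]) / (tm[idx + 1L] - tm[idx])
  out <- matrix(NA_real_, length(grid), 4L)
  for (i in seq_along(grid))
    out[i, ] <- quat_slerp(qs$quaternions[idx[i], ], qs$quaternions[idx[i] + 1L, ], u[i])
  quaternion_series(grid, out)
}

#' Uniform time grid covering the common span of several streams
#'
#' @param fs grid rate, Hz.
#' @param ... any mix of time vectors, `uniform_series`,
#'   `quaternion_series` or phone streams (`list(time=, values=)`).
#' @return numeric vector of grid times at rate `fs` inside the overlap.
#' @export
common_grid <- function(fs, ...) {
  spans <- lapply(list(...), function(s) {
    if (inherits(s, "uniform_series")) range(series_time(s))
    else if (inherits(s, "quaternion_series")) range(s$timestamps)
    else if (is.list(s) && !is.null(s$time)) range(s$time)
    else range(s)
  })
  lo <- max(vapply(spans, `[`, numeric(1), 1L))
  hi <- min(vapply(spans, `[`, numeric(1), 2L))
  if (hi <= lo) stop("data error: streams have no common time span")
  seq(ceiling(lo * fs) / fs, hi, by = 1 / fs)
}
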
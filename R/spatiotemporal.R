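# Per-cycle spatiotemporal gait parameters and summaries.
#
# Definitions: stride duration = time between two ipsilateral heel strikes;
# stance = heel strike to following ipsilateral toe-off; swing = toe-off to
# following ipsilateral heel strike; cadence = strides per minute
# (60 / stride duration); stride length = sagittal-plane (pelvis forward
# axis) displacement of the foot between consecutive ipsilateral heel
# strikes; stride speed = length / duration; double support = heel strike
# to following contralateral toe-off; step width = coronal-plane (pelvis
# right axis) distance between the feet at a heel strike.

#' Spatiotemporal parameters of one gait cycle
#'
#' @param cycle a `gait_cycle` (see [build_cycles()]).
#' @param foot_positions optional named list with per-side heel trajectories
#'   (`left`, `right`), each a [uniform_series()] of pelvis-expressed
#'   positions plus the pelvis origin path; see Details. When supplied as
#'   world-frame heel positions the sagittal displacement is taken
#'   directly.
#' @param fs sampling rate used only to validate durations, Hz (optional).
#' @return one-row data.frame: `side`, `source`, `stride_s`, `stance_s`,
#'   `swing_s`, `double_support_s`, `cadence_spm`, `length_m`, `speed_mps`,
#'   `width_m` (optional fields `NA` when inputs are missing).
#' @details `foot_positions$left`/`$right` must be `uniform_series` of heel
#'   positions in a frame whose axis 1 is the pelvis right axis and axis 2
#'   the forward axis, with whole-body translation retained (world frame or
#'   pelvis orientation applied to world positions); stride length is the
#'   forward-axis displacement between the bracketing heel strikes.
#' @export
compute_cycle_parameters <- function(cycle, foot_positions = NULL, fs = NULL) {
  stride <- cycle$end - cycle$start
  stance <- cycle$toe_off - cycle$start
  swing <- cycle$end - cycle$toe_off
  dsup <- if (is.na(cycle$contra_toe_off)) NA_real_
          else cycle$contra_toe_off - cycle$start
  len <- wid <- spd <- NA_real_
  if (!is.null(foot_positions)) {
    own <- foot_positions[[cycle$side]]
    if (!is.null(own)) {
      tm <- series_time(own)
      at <- function(s, tt, col) stats::approx(tm, s$values[, col], xout = tt,
                                               rule = 2, ties = "ordered")$y
      len <- abs(at(own, cycle$end, 2) - at(own, cycle$start, 2))
      spd <- len / stride
      other <- foot_positions[[setdiff(c("left", "right"), cycle$side)]]
      if (!is.null(other))
        wid <- abs(at(own, cycle$start, 1) - at(other, cycle$start, 1))
    }
  }
  data.frame(side = cycle$side, source = cycle$source,
             stride_s = stride, stance_s = stance, swing_s = swing,
             double_support_s = dsup, cadence_spm = 60 / stride,
             length_m = len, speed_mps = spd, width_m = wid)
}

#' Parameter table for a list of cycles
#'
#' @param cycles list of `gait_cycle`s.
#' @param foot_positions see [compute_cycle_parameters()].
#' @return data.frame with one row per cycle plus a `cycle_id` column.
#' @export
cycle_parameter_table <- function(cycles, foot_positions = NULL) {
  if (!length(cycles))
    return(data.frame(cycle_id = integer(0)))
  out <- do.call(rbind, lapply(cycles, compute_cycle_parameters,
                               foot_positions = foot_positions))
  cbind(cycle_id = seq_along(cycles), out)
}

#' Mean, SD and coefficient of variation summaries
#'
#' @param params data.frame from [cycle_parameter_table()].
#' @param by grouping columns (default side and source).
#' @return data.frame with one row per parameter x group: `n`, `mean`,
#'   `sd` (sample, n-1) and `cv_pct` = 100 * sd / mean (`NA` with a warning
#'   when the mean is zero).
#' @export
summarize_parameters <- function(params, by = c("side", "source")) {
  num_cols <- setdiff(names(params)[vapply(params, is.numeric, logical(1))],
                      "cycle_id")
  by <- intersect(by, names(params))
  key <- if (length(by)) interaction(params[by], drop = TRUE) else
    factor(rep("all", nrow(params)))
  out <- NULL
  for (g in levels(key)) {
    sub <- params[key == g, , drop = FALSE]
    for (p in num_cols) {
      v <- sub[[p]]; v <- v[is.finite(v)]
      if (length(v) < 2L) next
      m <- mean(v); s <- stats::sd(v)
      cv <- if (abs(m) < 1e-12) { warning("zero mean for ", p,
                                          "; CV undefined"); NA_real_ }
            else 100 * s / abs(m)
      out <- rbind(out, data.frame(group = g, parameter = p,
                                   n = length(v), mean = m, sd = s,
                                   cv_pct = cv))
    }
  }
  out %||% data.frame()
}

#' Fit the phone stride-length linear model
#'
#' Ordinary least squares for SL = a * f_stride + b * Var(a_vert) + c,
#' relating stride length to stride frequency and per-cycle vertical
#' acceleration variance.
#'
#' @param stride_length reference stride lengths, meters (>= 3 cycles).
#' @param f_stride stride frequencies, Hz (1 / stride duration).
#' @param acc_variance per-cycle variance of the (unfiltered,
#'   gravity-subtracted) vertical acceleration, (m/s^2)^2.
#' @return object of class `stride_length_model`: coefficients `a`, `b`,
#'   `c`, plus `r_squared`, `residual_sd`, `n`.
#' @export
fit_stride_length_model <- function(stride_length, f_stride, acc_variance) {
  n <- length(stride_length)
  if (n < 3L) stop("need at least 3 cycles to fit")
  if (length(f_stride) != n || length(acc_variance) != n)
    stop("feature lengths must match")
  if (any(!is.finite(c(stride_length, f_stride, acc_variance))))
    stop("features must be finite")
  X <- cbind(f_stride = f_stride, acc_variance = acc_variance, intercept = 1)
  qr_x <- qr(X)
  if (qr_x$rank < 3L) {
    sds <- apply(X[, 1:2], 2, stats::sd)
    bad <- names(sds)[which.min(sds)]
    stop("fit error: rank-deficient design (collinear feature: ", bad, ")")
  }
  beta <- qr.coef(qr_x, stride_length)
  fit <- as.numeric(X %*% beta)
  res <- stride_length - fit
  ss_tot <- sum((stride_length - mean(stride_length))^2)
  structure(list(a = beta[["f_stride"]], b = beta[["acc_variance"]],
                 c = beta[["intercept"]],
                 r_squared = if (ss_tot > 0) 1 - sum(res^2) / ss_tot else NA_real_,
                 residual_sd = if (n > 3L) sqrt(sum(res^2) / (n - 3L)) else 0,
                 n = n),
            class = "stride_length_model")
}

#' @export
print.stride_length_model <- function(x, ...) {
  cat(sprintf(
    "<stride_length_model> SL = %.4f*f + %.5f*Var + %.4f  (n=%d, R2=%.3f)\n",
    x$a, x$b, x$c, x$n, x$r_squared))
  invisible(x)
}

#' Predict stride length from phone features
#'
#' @param model a [fit_stride_length_model()] result.
#' @param f_stride stride frequency, Hz.
#' @param acc_variance vertical-acceleration variance, (m/s^2)^2.
#' @return predicted stride length(s), meters.
#' @export
predict_stride_length <- function(model, f_stride, acc_variance) {
  stopifnot(inherits(model, "stride_length_model"))
  model$a * f_stride + model$b * acc_variance + model$c
}
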
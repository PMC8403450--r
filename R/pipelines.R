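# Pipeline orchestration: end-to-end marker, IMU and phone analyses plus
# the validation run that compares two systems.

#' Marker (optoelectronic) analysis pipeline
#'
#' Low-pass filters the trajectories, expresses them in the per-sample
#' pelvis frame, runs the four kinematic event detectors and their
#' consensus, builds cycles and computes spatiotemporal parameters.
#' Stride length and step width use the heel trajectories rotated into the
#' pelvis axes with whole-body translation retained.
#'
#' @param markers world-frame [marker_set()].
#' @param model optional [kinematic_model()]; when supplied and
#'   `ik = TRUE`, marker-driven inverse kinematics is run on the
#'   pelvis-expressed trajectories.
#' @param lowpass marker low-pass cutoff, Hz (`NULL` to skip).
#' @param ik run inverse kinematics (slower).
#' @param ik_weights optional per-marker IK weights.
#' @param consensus_window consensus clustering window, seconds.
#' @return list with `events` (consensus), `method_events`, `cycles`,
#'   `parameters` (per-cycle data.frame), `summary`, `pose`
#'   (pose_trajectory or `NULL`), `markers_pelvis`, `foot_positions`.
#' @export
run_marker_pipeline <- function(markers, model = NULL, lowpass = 6,
                                ik = FALSE, ik_weights = NULL,
                                consensus_window = 0.05) {
  ms <- markers
  if (!is.null(lowpass))
    for (l in names(ms$trajectories))
      ms$trajectories[[l]] <- butterworth_lowpass(ms$trajectories[[l]],
                                                  4L, lowpass)
  frames <- pelvis_frames(ms)
  msp <- express_in_pelvis(ms, frames)
  methods <- c("interheel", "foot_com_velocity", "coordinate", "velocity")
  cand <- lapply(methods, function(m)
    suppressWarnings(detect_events_marker(msp, m)))
  names(cand) <- methods
  events <- consensus_events(cand, window = consensus_window)
  cycles <- build_cycles(events)
  foot <- rotated_heel_positions(ms, frames)
  params <- cycle_parameter_table(cycles, foot_positions = foot)
  pose <- if (ik && !is.null(model)) ik_markers(model, msp, ik_weights)
          else NULL
  list(events = events, method_events = cand, cycles = cycles,
       parameters = params,
       summary = if (nrow(params)) summarize_parameters(params) else NULL,
       pose = pose, markers_pelvis = msp, foot_positions = foot)
}

# Heel trajectories rotated into the pelvis axes but keeping whole-body
# translation: axis 1 = pelvis right, axis 2 = pelvis forward.
rotated_heel_positions <- function(ms, frames) {
  out <- list()
  for (side in c("left", "right")) {
    lab <- paste0("heel_", if (side == "left") "L" else "R")
    if (!lab %in% names(ms$trajectories)) next
    v <- ms$trajectories[[lab]]$values
    w <- v
    for (i in seq_len(nrow(v))) w[i, ] <- crossprod(frames[[i]]$R, v[i, ])
    out[[side]] <- uniform_series(w, fs = ms$fs, t0 = ms$t0, label = lab)
  }
  if (length(out)) out else NULL
}

#' Inertial (IMU) analysis pipeline
#'
#' Expresses per-segment sensor orientations relative to the pelvis sensor,
#' reconstructs the pose by orientation-driven inverse kinematics, rebuilds
#' foot-point trajectories by forward kinematics, detects gait events on
#' them, reconstructs forward travel from the stance-foot constraint and
#' computes spatiotemporal parameters.
#'
#' @param imus named list of [imu_recording()] (names = model segments);
#'   must include `pelvis` and per-side `foot_*` recordings with
#'   orientation streams.
#' @param model a [kinematic_model()].
#' @param consensus_window consensus clustering window, seconds.
#' @param lowpass low-pass cutoff applied to the reconstructed foot
#'   trajectories before event detection, Hz (`NULL` to skip).
#' @return list as for [run_marker_pipeline()] (plus `pose` always set).
#' @export
run_imu_pipeline <- function(imus, model, consensus_window = 0.05,
                             lowpass = 6) {
  if (is.null(imus$pelvis) || is.null(imus$pelvis$orientation))
    stop("configuration error: pelvis IMU orientation required")
  qp <- imus$pelvis$orientation
  tm <- qp$timestamps
  obs <- list()
  for (nm in setdiff(names(imus), "pelvis")) {
    if (!nm %in% names(model$segments)) next
    qs <- imus[[nm]]$orientation
    if (is.null(qs)) next
    rel <- quat_multiply(quat_conjugate(qp$quaternions), qs$quaternions)
    obs[[nm]] <- quaternion_series(tm, quat_normalize(rel))
  }
  pose <- ik_orientations(model, obs)
  fs <- 1 / stats::median(diff(tm))
  # model foot points in the pelvis frame via FK
  foot_labs <- intersect(c("heel_L", "toe_L", "heel_R", "toe_R"),
                         rownames_model_markers(model))
  traj <- lapply(foot_labs, function(l) matrix(NA_real_, length(tm), 3L))
  names(traj) <- foot_labs
  for (i in seq_along(tm)) {
    fk <- forward_kinematics(model, pose$angles[i, ], orientations = FALSE)
    for (l in foot_labs) traj[[l]][i, ] <- fk$markers[l, ]
  }
  msp <- marker_set(stats::setNames(lapply(foot_labs, function(l)
    uniform_series(traj[[l]], fs = fs, t0 = tm[1], label = l)), foot_labs))
  if (!is.null(lowpass) && lowpass < fs / 2)
    for (l in foot_labs)
      msp$trajectories[[l]] <- butterworth_lowpass(msp$trajectories[[l]],
                                                   4L, lowpass)
  methods <- c("interheel", "foot_com_velocity", "coordinate", "velocity")
  cand <- lapply(methods, function(m)
    suppressWarnings(detect_events_marker(msp, m, source = "imu")))
  names(cand) <- methods
  events <- consensus_events(cand, window = consensus_window, source = "imu")
  cycles <- build_cycles(events)
  # drop cycles reaching into the edge zone where zero-phase filtering and
  # the travel reconstruction are unreliable
  edge <- 0.25
  cycles <- Filter(function(cy)
    cy$start > tm[1] + edge && cy$end < tm[length(tm)] - edge, cycles)
  foot <- forward_path_foot_positions(msp, events)
  params <- cycle_parameter_table(cycles, foot_positions = foot)
  list(events = events, method_events = cand, cycles = cycles,
       parameters = params,
       summary = if (nrow(params)) summarize_parameters(params) else NULL,
       pose = pose, markers_pelvis = msp, foot_positions = foot)
}

# Reconstruct forward travel from pelvis-relative heel trajectories using
# the stance-foot constraint (the heel between its heel strike and the next
# ipsilateral toe-off is world-stationary), then return heel positions with
# the reconstructed translation restored.
forward_path_foot_positions <- function(msp, events) {
  tm <- msp$t0 + (seq_len(msp$n) - 1L) / msp$fs
  heel <- list(left = msp$trajectories$heel_L$values,
               right = msp$trajectories$heel_R$values)
  stance <- list(left = rep(FALSE, msp$n), right = rep(FALSE, msp$n))
  for (side in c("left", "right")) {
    hs <- events$time[events$kind == "heel_strike" & events$side == side]
    to <- events$time[events$kind == "toe_off" & events$side == side]
    for (h in hs) {
      nxt <- to[to > h]
      if (length(nxt)) stance[[side]][tm >= h & tm <= nxt[1]] <- TRUE
    }
  }
  dp <- numeric(msp$n)          # pelvis forward increments
  for (i in 2:msp$n) {
    incs <- c()
    for (side in c("left", "right"))
      if (stance[[side]][i] && stance[[side]][i - 1L])
        incs <- c(incs, -(heel[[side]][i, 2] - heel[[side]][i - 1L, 2]))
    dp[i] <- if (length(incs)) mean(incs) else dp[i - 1L]
  }
  y_pelvis <- cumsum(dp)
  out <- list()
  for (side in c("left", "right")) {
    w <- heel[[side]]
    w[, 2] <- w[, 2] + y_pelvis
    out[[side]] <- uniform_series(w, fs = msp$fs, t0 = msp$t0,
                                  label = paste0("heel_", side))
  }
  out
}

#' Pocket-smartphone analysis pipeline
#'
#' Synchronises the phone streams by linear (and, for vendor orientation,
#' spherical linear) interpolation, estimates orientation with the Madgwick
#' filter, derives the global vertical acceleration, detects gait events by
#' the peak/nadir procedure, builds cycles and computes the phone
#' spatiotemporal parameters. Stride length (and hence speed) requires a
#' fitted [fit_stride_length_model()].
#'
#' @param phone a [phone_recording()].
#' @param stride_model optional `stride_length_model`.
#' @param cfg a [fusion_config()].
#' @param fs analysis grid rate, Hz.
#' @param burn_in seconds excluded at the start (fusion convergence).
#' @param use_vendor_orientation use the recording's vendor orientation
#'   stream instead of recomputing via Madgwick.
#' @return list with `events`, `cycles`, `parameters`, `summary`,
#'   `a_vert`, `orientation`.
#' @export
run_phone_pipeline <- function(phone, stride_model = NULL,
                               cfg = fusion_config(), fs = 100, burn_in = 2,
                               use_vendor_orientation = FALSE) {
  ori <- if (use_vendor_orientation && !is.null(phone$orientation)) {
    grid <- common_grid(fs, phone$accelerometer, phone$orientation)
    resample_slerp(phone$orientation, grid)
  } else estimate_orientation(phone, cfg, fs = fs)
  a_vert <- global_vertical_acceleration(phone, ori, cfg)
  events <- suppressWarnings(detect_events_phone(a_vert, phone$side,
                                                 burn_in = burn_in))
  cycles <- build_cycles(events)
  params <- cycle_parameter_table(cycles)
  if (nrow(params)) {
    tm <- series_time(a_vert)
    av <- a_vert$values[, 1]
    params$acc_variance <- vapply(cycles, function(cy)
      stats::var(av[tm >= cy$start & tm <= cy$end]), numeric(1))
    params$f_stride <- 1 / params$stride_s
    if (!is.null(stride_model)) {
      params$length_m <- predict_stride_length(stride_model, params$f_stride,
                                               params$acc_variance)
      params$speed_mps <- params$length_m / params$stride_s
    }
  }
  list(events = events, cycles = cycles, parameters = params,
       summary = if (nrow(params)) summarize_parameters(
         params[setdiff(names(params), c("acc_variance", "f_stride"))]) else NULL,
       a_vert = a_vert, orientation = ori)
}

#' Calibrate the phone stride-length model on a synthetic corpus
#'
#' Runs the phone pipeline over seeded synthetic trials spanning a range of
#' cadences and stride lengths and regresses the commanded (truth) stride
#' length on stride frequency and vertical-acceleration variance. These are
#' calibration constants of this package's synthetic world, not published
#' coefficients.
#'
#' @param seed RNG seed for the corpus.
#' @param n_trials number of calibration trials.
#' @return a `stride_length_model`.
#' @export
calibrate_stride_length_model <- function(seed = 20L, n_trials = 6L) {
  sl <- fr <- av <- numeric(0)
  for (k in seq_len(n_trials)) {
    cfg <- gait_sim_config(
      cadence = 45 + 20 * (k - 1) / max(1, n_trials - 1),
      stride_length = 0.65 + 0.3 * ((k * 7L) %% n_trials) / max(1, n_trials - 1),
      n_strides = 8L, seed = seed + k)
    tr <- generate_trial(cfg)
    out <- run_phone_pipeline(tr$phones$left)
    p <- out$parameters
    if (!nrow(p)) next
    sl <- c(sl, rep(cfg$stride_length, nrow(p)))
    fr <- c(fr, p$f_stride); av <- c(av, p$acc_variance)
  }
  fit_stride_length_model(sl, fr, av)
}

#' Validate one system against a reference system
#'
#' Matches heel-strike events between the two systems, pairs the cycles
#' they bracket, and runs the full spatiotemporal agreement suite:
#' Bland-Altman with confidence intervals and a normality check per
#' parameter and side, plus Welch resolution tests of each parameter's bias
#' distribution against the pooled reference difference distributions.
#'
#' @param reference,test pipeline results (lists with `events` and
#'   `parameters`) or plain lists with those fields.
#' @param tolerance event-match tolerance, seconds.
#' @param ref_n assumed sample size of the pooled reference distributions.
#' @param parameters which parameter columns to analyse.
#' @return list with `pairs` (matched per-cycle table), `agreement`
#'   (per parameter/side: `bland_altman`, `normality`), `resolution`
#'   (per parameter/group Welch tests), `match` (the event match table).
#' @export
run_validation <- function(reference, test, tolerance = 0.15, ref_n = 100L,
                           parameters = c("stride_s", "stance_s", "swing_s",
                                          "double_support_s", "cadence_spm",
                                          "length_m", "speed_mps",
                                          "width_m")) {
  match <- match_events(reference$events, test$events, tolerance)
  rp <- reference$parameters; tp <- test$parameters
  hs_pairs <- match$pairs[match$pairs$kind == "heel_strike", , drop = FALSE]
  key <- function(t, side) paste(side, round(t, 4))
  ref_by_start <- stats::setNames(seq_len(nrow(rp)),
                                  key(vapply(reference$cycles, `[[`,
                                             numeric(1), "start"),
                                      rp$side))
  paired <- NULL
  for (i in seq_len(nrow(tp))) {
    cy <- test$cycles[[i]]
    m0 <- hs_pairs[abs(hs_pairs$test_time - cy$start) < 1e-9 &
                     hs_pairs$side == cy$side, , drop = FALSE]
    m1 <- hs_pairs[abs(hs_pairs$test_time - cy$end) < 1e-9 &
                     hs_pairs$side == cy$side, , drop = FALSE]
    if (nrow(m0) != 1L || nrow(m1) != 1L) next
    j <- ref_by_start[key(m0$reference_time, cy$side)]
    if (is.na(j)) next
    # the matched reference cycle must end at the matched end event
    if (abs(reference$cycles[[j]]$end - m1$reference_time) > 1e-9) next
    row <- data.frame(side = cy$side)
    for (p in parameters) {
      row[[paste0("ref_", p)]] <- if (p %in% names(rp)) rp[[p]][j] else NA_real_
      row[[paste0("test_", p)]] <- if (p %in% names(tp)) tp[[p]][i] else NA_real_
    }
    paired <- rbind(paired, row)
  }
  agreement <- list(); resolution <- list()
  if (!is.null(paired)) {
    for (p in parameters) {
      rv_all <- paired[[paste0("ref_", p)]]
      tv_all <- paired[[paste0("test_", p)]]
      if (is.null(rv_all)) next
      for (side in unique(paired$side)) {
        sel <- paired$side == side & is.finite(rv_all) & is.finite(tv_all)
        if (sum(sel) < 3L) next
        ba <- bland_altman(tv_all[sel], rv_all[sel])
        nt <- if (sum(sel) >= 8L && stats::sd(tv_all[sel] - rv_all[sel]) > 0)
          suppressWarnings(dagostino_pearson(tv_all[sel] - rv_all[sel]))
        else NULL
        agreement[[paste(p, side, sep = ".")]] <-
          list(parameter = p, side = side, bland_altman = ba, normality = nt)
      }
      sel <- is.finite(rv_all) & is.finite(tv_all)
      if (sum(sel) >= 3L) {
        d <- tv_all[sel] - rv_all[sel]
        for (grp in c("PDvsControl", "ONvsOFF")) {
          ref_tab <- reference_distributions(grp)
          ref_row <- ref_tab[ref_tab$parameter == p, , drop = FALSE]
          if (nrow(ref_row) == 1L && stats::sd(d) > 0)
            resolution[[paste(p, grp, sep = ".")]] <-
              resolution_test(d, as.list(ref_row), ref_n = ref_n)
        }
      }
    }
  }
  list(pairs = paired, agreement = agreement, resolution = resolution,
       match = match)
}

#' Waveform agreement between two pose trajectories
#'
#' Normalizes each common DoF to the gait cycles of the reference event
#' stream, averages the per-cycle waveforms per DoF and side, and computes
#' the Linear Fit Method statistics of the test system against the
#' reference, with group aggregates.
#'
#' @param ref_pose,test_pose [pose_trajectory()] objects on (possibly
#'   different) uniform grids covering the same trial.
#' @param cycles gait cycles (typically from the reference system).
#' @param dofs DoF labels to compare (default: intersection).
#' @return list with `per_dof` (data.frame of alpha1, alpha0, r_squared,
#'   mae in degrees), `lower`, `upper` ([aggregate_lfm()] results, when the
#'   groups are non-empty).
#' @export
compare_waveforms <- function(ref_pose, test_pose, cycles, dofs = NULL) {
  dofs <- dofs %||% intersect(ref_pose$labels, test_pose$labels)
  if (!length(dofs)) stop("no common DoF to compare")
  as_series <- function(pose, d)
    uniform_series(pose$angles[, d], fs = 1 / stats::median(diff(pose$time)),
                   t0 = pose$time[1], label = d)
  span_ok <- function(pose, cy)
    cy$start >= pose$time[1] - 1e-9 &&
      cy$end <= pose$time[length(pose$time)] + 1e-9
  per <- NULL
  for (d in dofs) {
    rs <- as_series(ref_pose, d); tsr <- as_series(test_pose, d)
    side <- if (grepl("_L$", d)) "left" else if (grepl("_R$", d)) "right" else ""
    use <- Filter(function(cy) (side == "" || cy$side == side) &&
                    span_ok(ref_pose, cy) && span_ok(test_pose, cy), cycles)
    if (!length(use)) next
    rw <- rowMeans(vapply(use, function(cy)
      normalize_gait_cycle(rs, cy, dof = d)$values, numeric(101L)))
    tw <- rowMeans(vapply(use, function(cy)
      normalize_gait_cycle(tsr, cy, dof = d)$values, numeric(101L)))
    if (stats::var(rw) == 0) next      # constant DoF carries no waveform
    lf <- linear_fit_method(rw * 180 / pi, tw * 180 / pi)
    per <- rbind(per, data.frame(
      dof = d, side = side, alpha1 = lf$alpha1, alpha0 = lf$alpha0,
      r_squared = lf$r_squared, mae = lf$mae,
      grp = if (grepl("hip|knee|ankle", d)) "lower" else "upper"))
  }
  out <- list(per_dof = per)
  for (g in c("lower", "upper"))
    if (!is.null(per) && any(per$grp == g))
      out[[g]] <- aggregate_lfm(per[per$grp == g, , drop = FALSE], g)
  out
}
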
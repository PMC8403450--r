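# Ground-truth gait simulator.
#
# One underlying kinematic trajectory drives every output stream, so the
# marker, IMU and phone pipelines can all be validated against the same
# known truth. The construction works backwards from foot-fall geometry:
# ankle paths relative to the pelvis are laid out so that each foot is
# exactly stationary in the world frame during stance (heel strike at the
# commanded times, stride length exact by construction), and hip/knee/ankle
# angles are recovered from those paths by closed-form two-link inverse
# kinematics. Markers and IMU orientations then come from the package's own
# forward kinematics, which guarantees FK/IK round-trip consistency. The
# pelvis carries a designed vertical oscillation whose acceleration has
# nadirs at heel-strike times, emulating the alternating peak/nadir
# structure that the thigh-pocket vertical acceleration shows in walking;
# the ipsilateral thigh swing provides the high/low peak alternation.
# Realistic gait phenomenology (impacts, soft tissue, pathology) is out of
# scope: internal consistency with known truth is the design goal.

#' Gait simulation configuration
#'
#' Defaults follow the cohort-level walking condition the package targets:
#' self-paced straight-line gait with stride duration near 1.09 s, stride
#' length near 0.86 m and stride speed near 0.80 m/s.
#'
#' @param cadence strides per minute.
#' @param stride_length commanded stride length, meters.
#' @param n_strides number of full strides simulated.
#' @param double_support_fraction fraction of the cycle between a heel
#'   strike and the contralateral toe-off (must be below 0.5).
#' @param step_width lateral distance between the feet, meters.
#' @param height participant stature, meters (drives model scaling).
#' @param marker_noise marker position noise SD, meters.
#' @param accel_noise accelerometer noise SD, m/s^2.
#' @param gyro_noise gyroscope noise SD, rad/s.
#' @param gyro_bias constant gyroscope bias magnitude, rad/s.
#' @param orientation_noise_deg IMU orientation noise SD, degrees.
#' @param fs_marker,fs_imu,fs_phone sampling rates, Hz.
#' @param clearance swing foot clearance, meters.
#' @param sway lateral ankle sway amplitude, meters.
#' @param pelvic_obliquity_deg pelvic roll amplitude, degrees (swing-side
#'   hip drop in late swing).
#' @param seed RNG seed (trials are bit-identical under a fixed seed).
#' @return object of class `gait_sim_config`.
#' @export
gait_sim_config <- function(cadence = 55.2, stride_length = 0.863,
                            n_strides = 10L, double_support_fraction = 0.1,
                            step_width = 0.17, height = 1.70,
                            marker_noise = 5e-4, accel_noise = 0.5,
                            gyro_noise = 0.02, gyro_bias = 0.01,
                            orientation_noise_deg = 0.3,
                            fs_marker = 120, fs_imu = 120, fs_phone = 100,
                            clearance = 0.08, sway = 0.008,
                            pelvic_obliquity_deg = 7, seed = 1L) {
  if (double_support_fraction >= 0.5 || double_support_fraction < 0)
    stop("parameter error: double_support_fraction must be in [0, 0.5)")
  if (cadence <= 0 || stride_length <= 0 || height <= 0 || n_strides < 2L)
    stop("parameter error: cadence, stride_length, height, n_strides")
  cfg <- list(cadence = cadence, stride_length = stride_length,
              n_strides = as.integer(n_strides),
              double_support_fraction = double_support_fraction,
              step_width = step_width, height = height,
              marker_noise = marker_noise, accel_noise = accel_noise,
              gyro_noise = gyro_noise, gyro_bias = gyro_bias,
              orientation_noise_deg = orientation_noise_deg,
              fs_marker = fs_marker, fs_imu = fs_imu, fs_phone = fs_phone,
              clearance = clearance, sway = sway,
              pelvic_obliquity_deg = pelvic_obliquity_deg,
              seed = as.integer(seed))
  structure(cfg, class = "gait_sim_config")
}

smoothstep <- function(s) s * s * (3 - 2 * s)

# phone centre of mass in the thigh frame (left side; x mirrored for right):
# shallow front pocket, just below and ahead of the hip joint
pocket_position <- function(hr) c(0.02, 0.04, -0.06) * hr

# Pelvis vertical oscillation, designed so that the pocket-level vertical
# acceleration shows the peak/nadir structure of walking: deep nadirs at
# heel strikes. The pelvis contribution is shared by both pockets and
# half-stride periodic (even stride harmonics); the construction therefore
# (i) cancels the even harmonics (k = 2, 4) of the deterministic thigh
# pendular term, computed analytically from one noise-free stride, and
# (ii) injects a -A*cos(4*pi*t/tau) acceleration whose nadirs fall exactly
# on the heel strikes. The stride-frequency (odd) component left in the
# signal is the ipsilateral swing itself, which boosts the peak preceding
# the ipsilateral heel strike and so provides the high/low peak
# alternation the phone detector keys on.
make_pelvis_bob <- function(cfg, accel_amp = 3.5) {
  tau <- 60 / cfg$cadence
  M <- 512L
  tf <- (0:(M - 1L)) / M * tau
  ts0 <- truth_state(cfg, tf, bob = function(t) rep(0, length(t)))
  hr <- cfg$height / 1.70
  pocket_local <- pocket_position(hr)
  al <- ts0$angles[, "hip_flexion_L"]
  gm <- ts0$angles[, "hip_adduction_L"]       # left sign: raw gamma = +value
  hip_off <- c(-0.09 * hr, 0, -0.05 * hr)
  zth <- vapply(seq_len(M), function(i) {
    Rp <- rot_elem(2L, ts0$rho[i])
    Rt <- Rp %*% rot_elem(1L, al[i]) %*% rot_elem(2L, gm[i])
    (Rp %*% hip_off + Rt %*% (pocket_local * c(-1, 1, 1)))[3]
  }, numeric(1))
  fsf <- M / tau
  acc <- (zth[c(2:M, 1L)] - 2 * zth + zth[c(M, 1:(M - 1L))]) * fsf^2
  cf <- stats::fft(acc) / M
  omega <- function(k) 2 * pi * k / tau
  # harmonic coefficients of the bob acceleration (complex, one-sided)
  b2 <- -accel_amp / 2 - cf[3L]               # k = 2 (index k + 1)
  b4 <- -cf[5L]                               # k = 4
  z2 <- -b2 / omega(2)^2
  z4 <- -b4 / omega(4)^2
  function(t)
    2 * Re(z2 * exp(2i * pi * 2 * t / tau)) +
    2 * Re(z4 * exp(2i * pi * 4 * t / tau))
}

# Ankle path relative to the pelvis for phase ph in [0,1) (heel strike at
# 0): stance sweeps forward excursion +a to -a linearly (world-stationary
# foot), swing returns with a clearance bump.
ankle_path <- function(ph, st, a, Lm, clearance) {
  y <- ifelse(ph < st, a * (1 - 2 * ph / st), {
    s <- (ph - st) / (1 - st); -a + 2 * a * smoothstep(s)
  })
  z <- ifelse(ph < st, -sqrt(Lm^2 - (a * (1 - 2 * ph / st))^2), {
    s <- (ph - st) / (1 - st); -sqrt(Lm^2 - a^2) + clearance * sin(pi * s)
  })
  cbind(y = y, z = z)
}

# Closed-form leg angles from an ankle target relative to the hip.
# Chain: hip Rx(alpha) Ry(gamma), knee Rx(-beta), thigh/shank lengths T, S.
leg_ik_closed_form <- function(d, thigh, shank) {
  r2 <- rowSums(d^2)
  cb <- (r2 - thigh^2 - shank^2) / (2 * thigh * shank)
  cb <- pmin(pmax(cb, -1), 0.9999)      # keep a hair of knee flexion
  beta <- acos(cb)                       # knee flexion (>= 0)
  v2 <- -shank * sin(beta)               # flexion draws the ankle backward
  v3 <- -thigh - shank * cos(beta)
  gamma <- asin(pmin(pmax(d[, 1] / v3, -1), 1))
  w3 <- v3 * cos(gamma)
  alpha <- atan2(d[, 3], d[, 2]) - atan2(w3, v2)
  alpha <- ((alpha + pi) %% (2 * pi)) - pi
  cbind(alpha = alpha, gamma = gamma, beta = beta)
}

# Evaluate the full truth state on an arbitrary time grid.
# Returns pelvis position, joint angles (clinical sign convention, matching
# default_model(legs = "both", arm = "right")) per frame.
truth_state <- function(cfg, t, bob = NULL) {
  tau <- 60 / cfg$cadence
  st <- 0.5 + cfg$double_support_fraction
  v <- cfg$stride_length / tau
  hr <- cfg$height / 1.70
  thigh <- 0.245 * cfg$height; shank <- 0.246 * cfg$height
  Lm <- 0.995 * (thigh + shank)
  a <- cfg$stride_length * st / 2
  if (a >= Lm * 0.98)
    stop("parameter error: stride length unreachable for this stature")
  if (is.null(bob)) bob <- make_pelvis_bob(cfg)
  z0 <- 0.05 * hr + sqrt(Lm^2 - a^2) + 0.039 * cfg$height
  pelvis <- cbind(0, v * t, z0 + bob(t))
  ang <- matrix(0, length(t), 16L)
  colnames(ang) <- c(
    "hip_flexion_L", "hip_adduction_L", "hip_rotation_L", "knee_flexion_L",
    "ankle_dorsiflexion_L",
    "hip_flexion_R", "hip_adduction_R", "hip_rotation_R", "knee_flexion_R",
    "ankle_dorsiflexion_R",
    "arm_flexion_R", "arm_adduction_R", "arm_rotation_R", "elbow_flexion_R",
    "pronation_R", "wrist_flexion_R")
  ph_l <- (t / tau) %% 1
  # pelvic obliquity: swing-side hip drops in late swing (roll about the
  # forward axis); this is what gives the thigh-pocket vertical
  # acceleration its pre-heel-strike boost.
  rho <- cfg$pelvic_obliquity_deg * pi / 180 * sin(2 * pi * ph_l - 0.188)
  for (side in c("L", "R")) {
    sx <- if (side == "L") -1 else 1
    ph <- if (side == "L") ph_l else (ph_l + 0.5) %% 1
    yz <- ankle_path(ph, st, a, Lm, cfg$clearance)
    x_rel <- sx * cfg$step_width / 2 + cfg$sway * sin(2 * pi * ph)
    # ankle target relative to the pelvis origin, world axes; express in
    # the rolled pelvis frame, then subtract the hip offset
    dw <- cbind(x_rel, yz[, "y"], yz[, "z"])
    cr <- cos(rho); sr <- sin(rho)
    d <- cbind(cr * dw[, 1] - sr * dw[, 3] - sx * 0.09 * hr,
               dw[, 2],
               sr * dw[, 1] + cr * dw[, 3] + 0.05 * hr)
    ik <- leg_ik_closed_form(d, thigh, shank)
    ang[, paste0("hip_flexion_", side)] <- ik[, "alpha"]
    ang[, paste0("hip_adduction_", side)] <- -sx * ik[, "gamma"]
    ang[, paste0("knee_flexion_", side)] <- ik[, "beta"]
    ang[, paste0("ankle_dorsiflexion_", side)] <- ik[, "beta"] - ik[, "alpha"]
  }
  ang[, "arm_flexion_R"] <- 0.25 * cos(2 * pi * ph_l)
  ang[, "arm_adduction_R"] <- 0.08 + 0.03 * sin(2 * pi * ph_l)
  ang[, "arm_rotation_R"] <- 0.05 * sin(2 * pi * ph_l + 0.7)
  ang[, "elbow_flexion_R"] <- 0.45 + 0.15 * cos(2 * pi * ph_l + 0.4)
  ang[, "pronation_R"] <- 0.2 + 0.1 * sin(2 * pi * ph_l + 1.1)
  ang[, "wrist_flexion_R"] <- 0.1 * sin(2 * pi * ph_l + 0.3)
  list(pelvis = pelvis, angles = ang, rho = rho, tau = tau, st = st, v = v)
}

truth_events_table <- function(cfg, t_end) {
  tau <- 60 / cfg$cadence
  st <- 0.5 + cfg$double_support_fraction
  ks <- 0:(cfg$n_strides + 1L)
  ev <- rbind(
    data.frame(time = ks * tau, kind = "heel_strike", side = "left"),
    data.frame(time = (ks + st) * tau, kind = "toe_off", side = "left"),
    data.frame(time = (ks + 0.5) * tau, kind = "heel_strike", side = "right"),
    data.frame(time = (ks + 0.5 + st) * tau, kind = "toe_off", side = "right"))
  ev <- ev[ev$time <= t_end + 1e-9, ]
  gait_events(ev$time, ev$kind, ev$side, source = "truth", method = "truth")
}

# numeric second derivative on a uniform grid (end samples replicated)
second_derivative <- function(x, fs) {
  n <- length(x)
  d2 <- (x[c(2:n, n)] - 2 * x + x[c(1, 1:(n - 1))]) * fs^2
  d2[1] <- d2[2]; d2[n] <- d2[n - 1]
  d2
}

# body-frame angular velocity from a quaternion sequence
gyro_from_quats <- function(q, fs) {
  n <- nrow(q)
  w <- matrix(0, n, 3)
  for (i in seq_len(n - 1L))
    w[i, ] <- quat_to_rotvec(quat_multiply(quat_conjugate(q[i, ]), q[i + 1L, ])) * fs
  w[n, ] <- w[n - 1L, ]
  w
}

#' Generate a synthetic gait trial
#'
#' Produces coherent marker, per-segment IMU and pocket-phone recordings
#' from one underlying kinematic trajectory, together with the exact truth
#' (events, per-cycle parameters, joint-angle trajectories). Deterministic
#' under a fixed `cfg$seed`.
#'
#' @param cfg a [gait_sim_config()].
#' @return object of class `synthetic_trial` with fields `config`, `model`
#'   (height-scaled [default_model()]), `markers` (world-frame
#'   [marker_set()]), `imus` (named list of [imu_recording()]),
#'   `phones` (list `left`/`right` of [phone_recording()]), and `truth`
#'   (list: `events`, `parameters`, `pose`, `pelvis`).
#' @export
generate_trial <- function(cfg = gait_sim_config()) {
  set.seed(cfg$seed)
  tau <- 60 / cfg$cadence
  t_end <- (cfg$n_strides + 0.6) * tau
  model <- scale_model(default_model(legs = "both", arm = "right"), cfg$height)

  # ---- marker stream (and truth pose on the marker grid) ----
  bob <- make_pelvis_bob(cfg)
  tm <- seq(0, t_end, by = 1 / cfg$fs_marker)
  ts <- truth_state(cfg, tm, bob = bob)
  nfr <- length(tm)
  mk_names <- rownames_model_markers(model)
  mk_arr <- array(NA_real_, c(nfr, 3L, length(mk_names)),
                  dimnames = list(NULL, NULL, mk_names))
  seg_names <- names(model$segments)
  seg_q <- lapply(seg_names, function(s) matrix(NA_real_, nfr, 4L))
  names(seg_q) <- seg_names
  seg_p <- lapply(seg_names, function(s) matrix(NA_real_, nfr, 3L))
  names(seg_p) <- seg_names
  for (i in seq_len(nfr)) {
    fk <- forward_kinematics(model, ts$angles[i, ], root_pos = ts$pelvis[i, ],
                             root_q = quat_from_axis_angle(c(0, 1, 0),
                                                           ts$rho[i]))
    mk_arr[i, , ] <- t(fk$markers[mk_names, ])
    for (s in seg_names) {
      seg_q[[s]][i, ] <- fk$segment_orientation[s, ]
      seg_p[[s]][i, ] <- fk$segment_origin[s, ]
    }
  }
  trajs <- stats::setNames(lapply(mk_names, function(l) {
    noisy <- mk_arr[, , l] +
      matrix(stats::rnorm(3L * nfr, 0, cfg$marker_noise), nfr)
    uniform_series(noisy, fs = cfg$fs_marker, t0 = 0, label = l)
  }), mk_names)
  markers <- marker_set(trajs)

  # ---- per-segment IMU recordings ----
  imus <- list()
  ori_sd <- cfg$orientation_noise_deg * pi / 180
  for (s in setdiff(seg_names, character(0))) {
    q <- seg_q[[s]]
    if (ori_sd > 0) {
      nz <- matrix(stats::rnorm(3L * nfr, 0, ori_sd), nfr)
      q <- quat_multiply(q, quat_from_rotvec(nz))
    }
    gyr <- gyro_from_quats(seg_q[[s]], cfg$fs_imu) +
      matrix(stats::rnorm(3L * nfr, 0, cfg$gyro_noise), nfr)
    acc_world <- apply(seg_p[[s]], 2L, second_derivative, fs = cfg$fs_imu)
    acc_world[, 3] <- acc_world[, 3] + 9.80665
    acc <- t(vapply(seq_len(nfr), function(i)
      as.numeric(crossprod(quat_to_matrix(seg_q[[s]][i, ]), acc_world[i, ])),
      numeric(3)))
    acc <- acc + matrix(stats::rnorm(3L * nfr, 0, cfg$accel_noise / 5), nfr)
    imus[[s]] <- imu_recording(
      s,
      uniform_series(acc, cfg$fs_imu, 0, "accelerometer"),
      uniform_series(gyr, cfg$fs_imu, 0, "gyroscope"),
      quaternion_series(tm, quat_normalize(q)))
  }

  # ---- pocket phones ----
  tp <- seq(0, t_end, by = 1 / cfg$fs_phone)
  tsp <- truth_state(cfg, tp, bob = bob)
  hr <- cfg$height / 1.70
  pocket_local <- pocket_position(hr)
  q_pocket <- quat_multiply(quat_from_axis_angle(c(0, 0, 1), 0.35),
                            quat_from_axis_angle(c(1, 0, 0), -1.75))
  phones <- list()
  for (side in c("left", "right")) {
    sx <- if (side == "left") -1 else 1
    al <- tsp$angles[, paste0("hip_flexion_", toupper(substr(side, 1, 1)))]
    gm <- -sx * tsp$angles[, paste0("hip_adduction_",
                                    toupper(substr(side, 1, 1)))]
    np <- length(tp)
    hip_off <- c(sx * 0.09 * hr, 0, -0.05 * hr)
    q_dev <- matrix(0, np, 4L)
    pocket <- matrix(0, np, 3L)
    for (i in seq_len(np)) {
      Rp <- rot_elem(2L, tsp$rho[i])
      Rt <- Rp %*% rot_elem(1L, al[i]) %*% rot_elem(2L, gm[i])
      q_dev[i, ] <- quat_multiply(quat_from_matrix(Rt), q_pocket)
      pocket[i, ] <- tsp$pelvis[i, ] + Rp %*% hip_off +
        Rt %*% (pocket_local * c(sx, 1, 1))
    }
    acc_world <- apply(pocket, 2L, second_derivative, fs = cfg$fs_phone)
    acc_world[, 3] <- acc_world[, 3] + 9.80665
    acc_dev <- t(vapply(seq_len(np), function(i)
      as.numeric(crossprod(quat_to_matrix(q_dev[i, ]), acc_world[i, ])),
      numeric(3)))
    acc_dev <- acc_dev + matrix(stats::rnorm(3L * np, 0, cfg$accel_noise), np)
    bias_dir <- stats::rnorm(3); bias_dir <- bias_dir / sqrt(sum(bias_dir^2))
    gyr_dev <- gyro_from_quats(q_dev, cfg$fs_phone) +
      matrix(stats::rnorm(3L * np, 0, cfg$gyro_noise), np) +
      matrix(rep(cfg$gyro_bias * bias_dir, each = np), np)
    phones[[side]] <- phone_recording(
      side,
      accelerometer = list(time = tp, values = acc_dev),
      gyroscope = list(time = tp + 0.0021, values = gyr_dev),
      orientation = quaternion_series(tp, quat_normalize(q_dev)))
  }

  # ---- truth bookkeeping ----
  events <- truth_events_table(cfg, t_end)
  cycles <- build_cycles(events)
  st <- 0.5 + cfg$double_support_fraction
  params <- cycle_parameter_table(cycles)
  params$length_m <- cfg$stride_length
  params$speed_mps <- cfg$stride_length / tau
  params$width_m <- cfg$step_width
  structure(list(config = cfg, model = model, markers = markers,
                 imus = imus, phones = phones,
                 truth = list(events = events, parameters = params,
                              pose = pose_trajectory(tm, ts$angles),
                              pelvis = list(time = tm, position = ts$pelvis))),
            class = "synthetic_trial")
}

#' @export
print.synthetic_trial <- function(x, ...) {
  cat(sprintf(
    "<synthetic_trial> %d strides @ %.1f strides/min, %d markers, %d IMUs, 2 phones\n",
    x$config$n_strides, x$config$cadence, length(x$markers$trajectories),
    length(x$imus)))
  invisible(x)
}

#' Degrade a synthetic trial
#'
#' Adds seeded marker occlusion gaps and extra measurement noise; the truth
#' fields are untouched.
#'
#' @param trial a [generate_trial()] result.
#' @param marker_dropout fraction of marker samples occluded, in `[0, 1)`.
#' @param extra_marker_noise additional marker noise SD, meters.
#' @param seed RNG seed for the degradation draws.
#' @return a `synthetic_trial` with degraded markers.
#' @export
degrade <- function(trial, marker_dropout = 0, extra_marker_noise = 0,
                    seed = trial$config$seed + 1L) {
  if (marker_dropout < 0 || marker_dropout >= 1)
    stop("marker_dropout must be in [0, 1)")
  if (marker_dropout == 0 && extra_marker_noise == 0) return(trial)
  set.seed(seed)
  ms <- trial$markers
  for (lab in names(ms$trajectories)) {
    n <- nrow(ms$trajectories[[lab]]$values)
    if (extra_marker_noise > 0)
      ms$trajectories[[lab]]$values <- ms$trajectories[[lab]]$values +
        matrix(stats::rnorm(3L * n, 0, extra_marker_noise), n)
    if (marker_dropout > 0) {
      gap <- stats::runif(n) < marker_dropout
      ms$gaps[, lab] <- ms$gaps[, lab] | gap
      ms$trajectories[[lab]]$values[gap, ] <- NA_real_
    }
  }
  trial$markers <- ms
  trial
}
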
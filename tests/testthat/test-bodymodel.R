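# Kinematic chain: scaling, forward kinematics, Cardan angles, pelvis
# frame, cycle normalization.

test_that("scaling is the identity at reference height and linear in height", {
  m <- default_model()
  expect_equal(scale_model(m, m$reference_height), m)
  m2 <- scale_model(m, 2 * m$reference_height)
  expect_equal(m2$segments$thigh_L$offset, 2 * m$segments$thigh_L$offset)
  expect_equal(m2$segments$foot_L$markers$heel_L,
               2 * m$segments$foot_L$markers$heel_L)
  expect_identical(m2$segments$thigh_L$sequence, m$segments$thigh_L$sequence)
  expect_error(scale_model(m, -1), "height")

  # FK marker distances scale exactly with the height ratio at a fixed pose
  set.seed(2)
  pose <- stats::setNames(runif(length(m$dof_names), -0.3, 0.3), m$dof_names)
  d1 <- dist(forward_kinematics(m, pose)$markers)
  d2 <- dist(forward_kinematics(scale_model(m, 1.87), pose)$markers)
  expect_equal(as.numeric(d2), as.numeric(d1) * 1.87 / 1.70,
               tolerance = 1e-12)
})

test_that("forward kinematics: neutral pose, planar chain, rigidity", {
  m <- default_model()
  fk <- forward_kinematics(m, neutral_pose(m))
  # neutral pose leaves pelvis markers at their local positions
  expect_equal(fk$markers["RASIS", ], c(0.12, 0, 0), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_error(forward_kinematics(m, c(hip_flexion_L = 0.1)), "missing DoF")

  # planar 2-link chain, links 0.4/0.4 m, hip 30 deg, knee 0:
  # distal joint at forward (T+S) sin(30), vertical -(T+S) cos(30)
  chain <- kinematic_model(list(
    root = list(parent = NA, offset = c(0, 0, 0), sequence = "",
                dof = character(0)),
    thigh = list(parent = "root", offset = c(0, 0, 0), sequence = "X",
                 dof = "hip"),
    shank = list(parent = "thigh", offset = c(0, 0, -0.4), sequence = "X",
                 dof = "knee", signs = -1,
                 markers = list(ankle = c(0, 0, -0.4)))))
  fk2 <- forward_kinematics(chain, c(hip = pi / 6, knee = 0))
  expect_equal(fk2$markers["ankle", ],
               c(0, 0.8 * sin(pi / 6), -0.8 * cos(pi / 6)),
               tolerance = 1e-12, ignore_attr = TRUE)

  # rigidity property: within-segment marker distances invariant
  set.seed(3)
  local_d <- dist(do.call(rbind, m$segments$shank_R$markers))
  for (i in 1:20) {
    pose <- stats::setNames(runif(length(m$dof_names), -1, 1), m$dof_names)
    glob <- forward_kinematics(m, pose)$markers
    expect_equal(as.numeric(dist(glob[names(m$segments$shank_R$markers), ])),
                 as.numeric(local_d), tolerance = 1e-12)
  }
})

test_that("Cardan decomposition inverts composition for all sequences", {
  for (sq in c("XYZ", "XZY", "YXZ", "YZX", "ZXY", "ZYX")) {
    expect_equal(cardan_angles(diag(3), sq), c(0, 0, 0))
    # pure rotation about the first axis
    a <- cardan_angles(cardan_matrix(c(40, 0, 0) * pi / 180, sq), sq)
    expect_equal(a, c(40, 0, 0) * pi / 180, tolerance = 1e-12)
  }
  set.seed(4)
  worst <- 0
  for (i in 1:1000) {
    sq <- sample(c("XYZ", "XZY", "YXZ", "YZX", "ZXY", "ZYX"), 1)
    q <- quat_normalize(rnorm(4))
    ang <- cardan_angles(q, sq)
    R2 <- cardan_matrix(ang, sq)
    worst <- max(worst, quat_angle(q, quat_from_matrix(R2)))
  }
  expect_lt(worst, 1e-9)

  # gimbal-lock warning attaches near +-90 deg middle angle
  Rg <- cardan_matrix(c(0.3, pi / 2 - 0.001, 0.2), "XYZ")
  expect_true(isTRUE(attr(cardan_angles(Rg, "XYZ"), "gimbal_warning")))
})

test_that("pelvis frame: canonical pose and equivariance", {
  lasis <- c(-0.12, 0, 0); rasis <- c(0.12, 0, 0)
  lpsis <- c(-0.05, -0.15, 0); rpsis <- c(0.05, -0.15, 0)
  f <- pelvis_frame(lasis, rasis, lpsis, rpsis)
  expect_equal(f$origin, c(0, 0, 0))
  expect_equal(f$R, diag(3), tolerance = 1e-12, ignore_attr = TRUE)

  # translation moves the origin only
  v <- c(1.2, -0.7, 0.4)
  f2 <- pelvis_frame(lasis + v, rasis + v, lpsis + v, rpsis + v)
  expect_equal(f2$origin, v)
  expect_equal(f2$R, f$R, tolerance = 1e-12)

  # rigid rotation rotates the frame
  set.seed(5)
  for (i in 1:10) {
    R <- quat_to_matrix(quat_normalize(rnorm(4)))
    f3 <- pelvis_frame(R %*% lasis, R %*% rasis, R %*% lpsis, R %*% rpsis)
    expect_equal(f3$R, R %*% f$R, tolerance = 1e-12)
  }
  expect_error(pelvis_frame(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(3, 0, 0)),
               "collinear")
})

test_that("express_in_pelvis: identity, inverse round trip, bounded walk", {
  tm <- (0:9) / 120
  ms <- marker_set(list(
    LASIS = uniform_series(cbind(-0.12, 0, 0)[rep(1, 10), ], 120),
    RASIS = uniform_series(cbind(0.12, 0, 0)[rep(1, 10), ], 120),
    LPSIS = uniform_series(cbind(-0.05, -0.15, 0)[rep(1, 10), ], 120),
    RPSIS = uniform_series(cbind(0.05, -0.15, 0)[rep(1, 10), ], 120),
    heel_L = uniform_series(matrix(rnorm(30), 10), 120)))
  fr <- pelvis_frames(ms)
  out <- express_in_pelvis(ms, fr)
  expect_equal(out$trajectories$heel_L$values, ms$trajectories$heel_L$values,
               tolerance = 1e-12)
  # round trip through a moving frame
  set.seed(6)
  fr2 <- lapply(1:10, function(i)
    list(origin = rnorm(3), R = quat_to_matrix(quat_normalize(rnorm(4)))))
  back <- express_in_pelvis(express_in_pelvis(ms, fr2), fr2, invert = TRUE)
  expect_equal(back$trajectories$heel_L$values, ms$trajectories$heel_L$values,
               tolerance = 1e-12)

  # a 10 m walk stays bounded in pelvis coordinates
  tr <- generate_trial(gait_sim_config(n_strides = 10L, seed = 21))
  msp <- express_in_pelvis(tr$markers, pelvis_frames(tr$markers))
  travel <- diff(range(tr$markers$trajectories$heel_L$values[, 2]))
  expect_gt(travel, 8)
  expect_lt(diff(range(msp$trajectories$heel_L$values[, 2])), 1.5)
})

test_that("gait-cycle normalization: ramps, constants, sinusoids", {
  fs <- 120
  tm <- (0:499) / fs
  cyc <- structure(list(side = "left", start = 0.5, end = 1.72,
                        toe_off = 1.2, contra_toe_off = NA, source = ""),
                   class = "gait_cycle")
  ramp <- uniform_series(2 * tm + 1, fs)
  w <- normalize_gait_cycle(ramp, cyc, dof = "knee_flexion_L")
  expect_length(w$values, 101L)
  expect_equal(w$values, seq(2 * 0.5 + 1, 2 * 1.72 + 1, length.out = 101),
               tolerance = 1e-9)
  const <- uniform_series(rep(0.3, 500), fs)
  expect_equal(normalize_gait_cycle(const, cyc)$values, rep(0.3, 101))
  # sinusoid with period equal to the cycle duration, sampled densely so
  # the piecewise-linear interpolation error is below the tolerance
  per <- cyc$end - cyc$start
  fs_hi <- 5000
  tm_hi <- (0:(2.5 * fs_hi)) / fs_hi
  sine <- uniform_series(sin(2 * pi * (tm_hi - cyc$start) / per), fs_hi)
  wn <- normalize_gait_cycle(sine, cyc)
  expect_lt(max(abs(wn$values - sin(2 * pi * seq(0, 1, length.out = 101)))),
            1e-6)
  expect_error(normalize_gait_cycle(ramp, structure(
    list(side = "left", start = -1, end = 2), class = "gait_cycle")), "range")
})
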
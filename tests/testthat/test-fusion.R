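# Madgwick orientation estimation and vertical acceleration.

g0 <- 9.80665

test_that("madgwick_step: equilibrium, norm preservation, gyro reduction", {
  # level and stationary: exact fixed point
  q <- madgwick_step(c(1, 0, 0, 0), c(0, 0, 0), c(0, 0, g0), 0.01)
  expect_equal(q, c(1, 0, 0, 0), tolerance = 1e-15)

  # beta = 0 equals pure quaternion-rate integration (closed form)
  cfg0 <- fusion_config(beta = 0)
  q <- c(1, 0, 0, 0); omega <- 0.7; dt <- 1e-3; N <- 1000L
  for (i in seq_len(N)) q <- madgwick_step(q, c(0, 0, omega), c(0, 0, g0),
                                           dt, cfg0)
  expect_lt(quat_angle(q, quat_from_axis_angle(c(0, 0, 1), omega * N * dt)),
            1e-6)

  # unit norm preserved on random inputs; beta = 0 equals the explicit
  # gyro-integration oracle step by step
  set.seed(5)
  q <- quat_normalize(rnorm(4)); qi <- q
  for (i in 1:200) {
    w <- rnorm(3); a <- rnorm(3) * 3 + c(0, 0, g0)
    q <- madgwick_step(q, w, a, 0.01, cfg0)
    qi <- quat_normalize(qi + 0.5 * quat_multiply(qi, c(0, w)) * 0.01)
    expect_equal(sqrt(sum(q^2)), 1, tolerance = 1e-9)
  }
  expect_equal(q, qi, tolerance = 1e-12)
  expect_error(madgwick_step(c(2, 0, 0, 0), c(0, 0, 0), c(0, 0, g0), 0.01),
               "unit")
})

test_that("static convergence: tilted sensor reaches true vertical", {
  # 30 deg tilt about x, q0 = identity, beta = 0.1, 10 s at 100 Hz
  qt <- quat_from_axis_angle(c(1, 0, 0), 30 * pi / 180)
  acc <- quat_rotate(quat_conjugate(qt), c(0, 0, g0))
  cfg <- fusion_config(beta = 0.1, q0 = c(1, 0, 0, 0))
  q <- c(1, 0, 0, 0)
  for (i in 1:1000) q <- madgwick_step(q, c(0, 0, 0), acc, 0.01, cfg)
  vert <- quat_rotate(q, acc)
  err <- acos(min(1, vert[3] / sqrt(sum(vert^2)))) * 180 / pi
  expect_lt(err, 0.5)

  # monotone error decrease after burn-in for assorted initial tilts
  for (tilt in c(10, 35, 60)) {
    qt <- quat_from_axis_angle(c(1, 1, 0), tilt * pi / 180)
    acc <- quat_rotate(quat_conjugate(qt), c(0, 0, g0))
    q <- c(1, 0, 0, 0)
    errs <- numeric(600)
    for (i in 1:600) {
      q <- madgwick_step(q, c(0, 0, 0), acc, 0.01, cfg)
      v <- quat_rotate(q, acc)
      errs[i] <- acos(max(-1, min(1, v[3] / g0)))
    }
    expect_lt(errs[600] * 180 / pi, 0.5)
    # error shrinks through the burn-in and never rebounds materially
    expect_lt(errs[400], errs[200])
    expect_lt(max(errs[400:600]), errs[200] + 1e-3)
  }
})

test_that("estimate_orientation recovers a static noisy recording", {
  set.seed(11)
  n <- 1000L; tm <- (0:(n - 1)) / 100
  qt <- quat_from_axis_angle(c(1, 0.3, 0), 0.4)
  acc <- matrix(rep(quat_rotate(quat_conjugate(qt), c(0, 0, g0)), each = n),
                n) + matrix(rnorm(3 * n, 0, 0.05), n)
  gyr <- matrix(rnorm(3 * n, 0, 0.002), n)
  rec <- phone_recording("left", list(time = tm, values = acc),
                         list(time = tm, values = gyr))
  est <- estimate_orientation(rec, fusion_config(), fs = 100)
  idx <- est$timestamps > 2
  errs <- vapply(which(idx), function(i) {
    v <- quat_rotate(est$quaternions[i, ],
                     quat_rotate(quat_conjugate(qt), c(0, 0, 1)))
    acos(max(-1, min(1, v[3])))
  }, numeric(1))
  expect_lt(max(errs) * 180 / pi, 0.5)

  # gyro-only fold equals manual composition of madgwick_step
  cfg0 <- fusion_config(beta = 0, q0 = c(1, 0, 0, 0))
  est0 <- estimate_orientation(rec, cfg0, grid = tm)
  q <- c(1, 0, 0, 0); dt <- c(diff(tm)[1], diff(tm))
  for (i in seq_len(n)) {
    q <- madgwick_step(q, gyr[i, ], acc[i, ], dt[i], cfg0)
    if (i %in% c(1L, 500L, n))
      expect_equal(est0$quaternions[i, ], q, tolerance = 1e-12)
  }
})

test_that("frame rotation of the sensor leaves the estimated vertical invariant", {
  set.seed(12)
  n <- 800L; tm <- (0:(n - 1)) / 100
  # gently moving sensor
  gyr <- cbind(0.3 * sin(2 * pi * tm), 0.2 * cos(2 * pi * tm), 0)
  q_true <- matrix(0, n, 4); q <- c(1, 0, 0, 0)
  acc <- matrix(0, n, 3)
  for (i in 1:n) {
    q <- quat_normalize(q + 0.5 * quat_multiply(q, c(0, gyr[i, ])) * 0.01)
    q_true[i, ] <- q
    acc[i, ] <- quat_rotate(quat_conjugate(q), c(0, 0, g0))
  }
  qstar <- quat_from_axis_angle(c(0.2, 1, 0.5), 0.9)
  Rs <- quat_to_matrix(qstar)
  rec1 <- phone_recording("left", list(time = tm, values = acc),
                          list(time = tm, values = gyr))
  rec2 <- phone_recording("left",
                          list(time = tm, values = acc %*% Rs),
                          list(time = tm, values = gyr %*% Rs))
  e1 <- estimate_orientation(rec1, fusion_config(), grid = tm)
  e2 <- estimate_orientation(rec2, fusion_config(), grid = tm)
  idx <- which(tm > 2)
  errs <- vapply(idx, function(i) {
    v1 <- quat_rotate(e1$quaternions[i, ], acc[i, ])
    v2 <- quat_rotate(e2$quaternions[i, ], as.numeric(crossprod(Rs, acc[i, ])))
    acos(max(-1, min(1, sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2)))))
  }, numeric(1))
  expect_lt(max(errs) * 180 / pi, 1)
})

test_that("global vertical acceleration recovers analytic motion", {
  n <- 2000L; tm <- (0:(n - 1)) / 100
  A <- 0.05; f <- 1.3
  z <- A * sin(2 * pi * f * tm)
  a_z <- -A * (2 * pi * f)^2 * sin(2 * pi * f * tm)

  # identity orientation
  rec <- phone_recording("left",
                         list(time = tm, values = cbind(0, 0, a_z + g0)),
                         list(time = tm, values = matrix(0, n, 3)))
  ori <- quaternion_series(tm, matrix(rep(c(1, 0, 0, 0), each = n), n))
  got <- global_vertical_acceleration(rec, ori)
  expect_lt(max(abs(got$values[, 1] - a_z)), 0.02 * max(abs(a_z)))

  # same motion, sensor pitched 45 deg with known orientation
  qp <- quat_from_axis_angle(c(1, 0, 0), pi / 4)
  accs <- t(vapply(seq_len(n), function(i)
    quat_rotate(quat_conjugate(qp), c(0, 0, a_z[i] + g0)), numeric(3)))
  rec2 <- phone_recording("left", list(time = tm, values = accs),
                          list(time = tm, values = matrix(0, n, 3)))
  ori2 <- quaternion_series(tm, matrix(rep(qp, each = n), n))
  got2 <- global_vertical_acceleration(rec2, ori2)
  expect_lt(max(abs(got2$values[, 1] - a_z)), 0.02 * max(abs(a_z)))

  # stationary: zero within noise
  set.seed(3)
  recs <- phone_recording("left",
                          list(time = tm,
                               values = matrix(rep(c(0, 0, g0), each = n), n) +
                                 matrix(rnorm(3 * n, 0, 0.1), n)),
                          list(time = tm, values = matrix(0, n, 3)))
  gots <- global_vertical_acceleration(recs, ori)
  expect_lt(abs(mean(gots$values[, 1])), 0.02)
})
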
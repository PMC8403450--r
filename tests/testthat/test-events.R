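# Gait event detection, consensus, matching and cycle building.

test_that("marker detectors find nothing on a standing trace", {
  n <- 200L
  static <- marker_set(list(
    heel_L = uniform_series(matrix(rep(c(-0.08, 0.1, -0.75), each = n), n), 120),
    toe_L = uniform_series(matrix(rep(c(-0.08, 0.3, -0.75), each = n), n), 120),
    heel_R = uniform_series(matrix(rep(c(0.08, 0.1, -0.75), each = n), n), 120),
    toe_R = uniform_series(matrix(rep(c(0.08, 0.3, -0.75), each = n), n), 120)))
  for (meth in c("interheel", "foot_com_velocity", "coordinate", "velocity"))
    expect_warning(ev <- detect_events_marker(static, meth), "no gait events")
})

test_that("coordinate method hits analytic sinusoidal extrema", {
  fs <- 120; n <- 1200L
  tm <- (0:(n - 1)) / fs
  f <- 0.9
  heel_y <- 0.25 * sin(2 * pi * f * tm)
  toe_y <- 0.25 * sin(2 * pi * f * tm) + 0.2
  z <- rep(-0.7, n)
  mk <- function(y) uniform_series(cbind(0, y, z), fs)
  ms <- marker_set(list(heel_L = mk(heel_y), toe_L = mk(toe_y),
                        heel_R = mk(-heel_y), toe_R = mk(-toe_y + 0.4)))
  ev <- detect_events_marker(ms, "coordinate")
  hs_l <- ev$time[ev$kind == "heel_strike" & ev$side == "left"]
  # analytic maxima of sin at (k + 1/4) / f
  expected <- (0:8 + 0.25) / f
  expected <- expected[expected < max(tm)]
  for (tt in hs_l) expect_lt(min(abs(expected - tt)), 1.01 / fs)
  to_l <- ev$time[ev$kind == "toe_off" & ev$side == "left"]
  exp_to <- (0:8 + 0.75) / f; exp_to <- exp_to[exp_to < max(tm)]
  for (tt in to_l) expect_lt(min(abs(exp_to - tt)), 1.01 / fs)
})

test_that("all four methods hit truth heel strikes on a noise-free walk", {
  tr <- generate_trial(gait_sim_config(n_strides = 6L, seed = 42,
                                       marker_noise = 0))
  msp <- express_in_pelvis(tr$markers, pelvis_frames(tr$markers))
  truth <- tr$truth$events
  errs_by_method <- list()
  for (meth in c("interheel", "foot_com_velocity", "coordinate", "velocity")) {
    ev <- detect_events_marker(msp, meth)
    hs <- ev[ev$kind == "heel_strike", ]
    expect_gt(nrow(hs), 8L)
    errs <- vapply(seq_len(nrow(hs)), function(i) {
      tt <- truth$time[truth$kind == "heel_strike" &
                         truth$side == hs$side[i]]
      min(abs(tt - hs$time[i]))
    }, numeric(1))
    expect_lt(stats::median(errs), 0.025)
    errs_by_method[[meth]] <- stats::median(errs)
  }
  # consensus at least as good as the best single method plus one sample
  cands <- lapply(c("interheel", "foot_com_velocity", "coordinate",
                    "velocity"), function(m) detect_events_marker(msp, m))
  cons <- consensus_events(cands)
  hs <- cons[cons$kind == "heel_strike", ]
  errs <- vapply(seq_len(nrow(hs)), function(i) {
    tt <- truth$time[truth$kind == "heel_strike" & truth$side == hs$side[i]]
    min(abs(tt - hs$time[i]))
  }, numeric(1))
  expect_lte(stats::median(errs),
             min(unlist(errs_by_method)) + 1 / tr$markers$fs)

  # per-side alternation of the consensus stream
  for (side in c("left", "right")) {
    kinds <- cons$kind[cons$side == side]
    expect_true(all(kinds[-1] != kinds[-length(kinds)]))
  }
})

test_that("consensus clustering follows the stated decision rule", {
  mk_ev <- function(times, kind = "heel_strike", side = "left")
    gait_events(times, kind, side, method = "m")
  four <- replicate(4, mk_ev(c(1.0, 2.1, 3.2)), simplify = FALSE)
  out <- consensus_events(four)
  expect_equal(out$time, c(1.0, 2.1, 3.2))

  # cluster median; singleton outlier dropped
  out2 <- consensus_events(list(mk_ev(c(1.000)), mk_ev(c(1.008)),
                                mk_ev(c(1.004)), mk_ev(c(1.300))),
                           window = 0.05)
  expect_equal(out2$time, 1.004)

  # one method silent, three agree: still emitted
  out3 <- consensus_events(list(mk_ev(numeric(0)), mk_ev(1.0), mk_ev(1.01),
                                mk_ev(0.99)))
  expect_equal(nrow(out3), 1L)

  # order invariance
  set.seed(10)
  lists <- list(mk_ev(c(1.00, 2.00)), mk_ev(c(1.01, 2.02)),
                mk_ev(c(0.99, 1.98)), mk_ev(c(1.02, 2.01)))
  ref <- consensus_events(lists)
  for (i in 1:5) {
    perm <- sample(4)
    expect_equal(consensus_events(lists[perm]), ref)
  }
  expect_error(consensus_events(list(), window = 0.05), "at least one")
  expect_error(consensus_events(lists, window = -1), "positive")
})

test_that("phone detector: flat signal, analytic waveform, synthetic trial", {
  flat <- uniform_series(rep(0, 800), fs = 100)
  expect_warning(ev <- detect_events_phone(flat, "left"), "fewer than 2")
  expect_equal(nrow(ev), 0L)

  # alternating-amplitude waveform: sum of 1 Hz and 2 Hz sinusoids.
  # The detector low-passes at 2 Hz first, so the analytic oracle is the
  # same sum with each component scaled by the zero-phase (squared)
  # magnitude response at its frequency.
  fs <- 100; tm <- (0:2999) / fs
  x <- function(t) -2.4 * cos(2 * pi * 2 * t) - 1.0 * sin(2 * pi * t)
  co <- butter_lowpass(4, 2, fs)
  gain2 <- function(f) {
    z <- exp(-2i * pi * f / fs)
    Mod(sum(co$b * z^(seq_along(co$b) - 1)) /
          sum(co$a * z^(seq_along(co$a) - 1)))^2
  }
  xf <- function(t) -2.4 * gain2(2) * cos(2 * pi * 2 * t) -
    1.0 * gain2(1) * sin(2 * pi * t)
  # analytic extrema of one period of the filtered waveform
  tg <- seq(0, 1, by = 1e-5)
  v <- xf(tg)
  pk_i <- which(diff(sign(diff(v))) < 0) + 1L
  nd_i <- which(diff(sign(diff(v))) > 0) + 1L
  high_pk <- tg[pk_i[which.max(v[pk_i])]]
  # the expected heel-strike nadir is the first analytic nadir after the
  # taller peak; the other nadir is the toe-off
  nads <- tg[nd_i]
  hs_nadir <- min(nads[nads > high_pk] %% 1,
                  if (!any(nads > high_pk)) (nads[1] + 1) %% 1 else Inf)
  to_nadir <- setdiff(round(nads, 6), round(hs_nadir, 6))[1]
  s <- uniform_series(x(tm), fs)
  ev <- detect_events_phone(s, "right", burn_in = 1)
  expect_gt(nrow(ev), 20L)
  hs <- ev$time[ev$kind == "heel_strike"]
  to <- ev$time[ev$kind == "toe_off"]
  expect_true(all(vapply(hs, function(t0)
    min(abs((t0 - hs_nadir) - round(t0 - hs_nadir))) <= 1.01 / fs,
    logical(1))))
  expect_true(all(vapply(to, function(t0)
    min(abs((t0 - to_nadir) - round(t0 - to_nadir))) <= 1.01 / fs,
    logical(1))))

  # synthetic thigh-pocket trace with default noise (0.5 m/s^2)
  tr <- generate_trial(gait_sim_config(n_strides = 10L, seed = 31))
  ph <- tr$phones$left
  ori <- estimate_orientation(ph, fusion_config(), fs = 100)
  av <- global_vertical_acceleration(ph, ori)
  ev2 <- detect_events_phone(av, "left")
  truth <- tr$truth$events
  tt <- truth$time[truth$kind == "heel_strike" & truth$side == "left"]
  ttw <- tt[tt > 2.5 & tt < max(series_time(av)) - 0.2]
  mt <- match_events(truth[truth$side == "left" & truth$time > 2.5, ], ev2,
                     0.15)
  hs_pairs <- mt$pairs[mt$pairs$kind == "heel_strike", ]
  expect_gte(nrow(hs_pairs) / length(ttw), 0.95)
  expect_lte(stats::median(abs(hs_pairs$offset)), 0.040)
})

test_that("event matching is greedy nearest, one-to-one, tolerance-bound", {
  ev <- function(times, side = "left", kind = "heel_strike")
    gait_events(times, kind, side, source = "truth")
  a <- ev(c(1, 2, 3))
  m1 <- match_events(a, a)
  expect_equal(nrow(m1$pairs), 3L)
  expect_equal(m1$pairs$offset, rep(0, 3))

  m2 <- match_events(a, ev(3.5), tolerance = 0.2)
  expect_equal(nrow(m2$pairs), 0L)
  expect_equal(nrow(m2$unmatched_test), 1L)

  # two test events near one reference: only the nearer matches
  m3 <- match_events(ev(1.00), ev(c(0.95, 1.02)), tolerance = 0.2)
  expect_equal(nrow(m3$pairs), 1L)
  expect_equal(m3$pairs$test_time, 1.02)

  # exhaustive small-case oracle: 3 ref x 3 test, greedy-by-distance
  set.seed(11)
  for (rep in 1:25) {
    r <- sort(runif(3, 0, 3)); s <- sort(runif(3, 0, 3))
    got <- match_events(ev(r), ev(s), tolerance = 0.4)
    # oracle: sort all pairs by |dt|, take greedily
    cand <- expand.grid(i = 1:3, j = 1:3)
    cand$d <- abs(r[cand$i] - s[cand$j])
    cand <- cand[cand$d <= 0.4, ]
    cand <- cand[order(cand$d), ]
    ti <- tj <- logical(3); pairs <- 0L
    for (k in seq_len(nrow(cand))) {
      if (!ti[cand$i[k]] && !tj[cand$j[k]]) {
        ti[cand$i[k]] <- tj[cand$j[k]] <- TRUE
        pairs <- pairs + 1L
      }
    }
    expect_equal(nrow(got$pairs), pairs)
    expect_lte(nrow(got$pairs), 3L)
    if (nrow(got$pairs)) expect_lte(max(abs(got$pairs$offset)), 0.4)
  }
  expect_error(match_events(a, a, tolerance = 0), "positive")
})

test_that("cycle building enforces the HS-TO-HS pattern", {
  ev <- gait_events(c(1.0, 1.65, 2.1), c("heel_strike", "toe_off",
                                         "heel_strike"), "left")
  cyc <- build_cycles(ev)
  expect_length(cyc, 1L)
  expect_equal(cyc[[1]]$start, 1.0)
  expect_equal(cyc[[1]]$toe_off, 1.65)
  expect_equal(cyc[[1]]$end, 2.1)

  # missing toe-off: dropped with a logged reason
  ev2 <- gait_events(c(1.0, 2.1, 2.7, 3.2),
                     c("heel_strike", "heel_strike", "toe_off", "heel_strike"),
                     "left")
  cyc2 <- build_cycles(ev2)
  expect_length(cyc2, 1L)
  expect_match(attr(cyc2, "dropped")[1], "toe-offs")

  # generator bookkeeping: one cycle per consecutive ipsilateral HS pair
  tr <- generate_trial(gait_sim_config(n_strides = 6L, seed = 12))
  cyc3 <- build_cycles(tr$truth$events)
  hs_l <- sum(tr$truth$events$kind == "heel_strike" &
                tr$truth$events$side == "left")
  hs_r <- sum(tr$truth$events$kind == "heel_strike" &
                tr$truth$events$side == "right")
  expect_length(cyc3, (hs_l - 1L) + (hs_r - 1L))
})
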
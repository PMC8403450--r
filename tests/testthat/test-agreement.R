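# Agreement statistics: Bland-Altman, normality, Welch, MAE, LFM and the
# published-fixture aggregation.

test_that("Bland-Altman closed-form cases", {
  ba0 <- bland_altman(c(4, 5, 6), c(4, 5, 6))
  expect_equal(ba0$bias, 0)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))

  # d = {-1, 0, 1}: bias 0, sd 1, LoA +-1.96, CI(bias) +-4.303/sqrt(3)
  ba <- bland_altman(c(-1, 0, 1) + 5, c(5, 5, 5))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-1.96, 1.96))
  tq <- stats::qt(0.975, 2)
  expect_equal(ba$ci_bias, c(-1, 1) * tq / sqrt(3), tolerance = 1e-9)
  expect_equal(round(ba$ci_bias[2], 3), 2.484)
  expect_equal(ba$ci_loa_upper, 1.96 + c(-1, 1) * tq * sqrt(3 / 3),
               tolerance = 1e-9)

  ba2 <- bland_altman(c(1, 2, 3, 4) + 0.7, c(1, 2, 3, 4))
  expect_equal(ba2$bias, 0.7)
  expect_equal(c(ba2$loa_lower, ba2$loa_upper), c(0.7, 0.7))
  expect_error(bland_altman(1:2, 1:2), "n >= 3")
  expect_error(bland_altman(1:4, 1:3), "paired")

  # LoA half-width / sd ratio is exactly 1.96; bias CI shrinks as 1/sqrt(n)
  set.seed(17)
  widths <- vapply(c(10, 40, 160), function(n) {
    d <- rnorm(n)
    b <- bland_altman(d, rep(0, n))
    expect_equal((b$loa_upper - b$bias) / b$sd_diff, 1.96, tolerance = 1e-12)
    diff(b$ci_bias) / b$sd_diff
  }, numeric(1))
  expect_equal(widths[1] / widths[2], 2, tolerance = 0.15)
  expect_equal(widths[2] / widths[3], 2, tolerance = 0.15)
})

test_that("difference-versus-mean table matches the per-pair oracle", {
  expect_equal(mean_vs_diff_points(2, 0), data.frame(mean = 1, difference = 2))
  x <- c(1.2, 3.4); y <- x
  expect_equal(mean_vs_diff_points(x, y)$difference, c(0, 0))
  set.seed(18)
  x <- rnorm(50); y <- rnorm(50)
  tab <- mean_vs_diff_points(x, y)
  for (i in c(1, 25, 50)) {
    expect_equal(tab$mean[i], (x[i] + y[i]) / 2)
    expect_equal(tab$difference[i], x[i] - y[i])
  }
})

test_that("D'Agostino-Pearson omnibus matches a textbook oracle", {
  # perfectly symmetric sample: zero skewness component
  d <- c(-3, -2, -1, 0, 1, 2, 3) + 10
  r <- suppressWarnings(dagostino_pearson(rep(d, 4)))
  expect_equal(r$z_skewness, 0)

  # independent textbook-formula oracle, written out separately
  oracle_k2 <- function(x) {
    n <- length(x)
    m <- mean(x); s2 <- mean((x - m)^2)
    g1 <- mean((x - m)^3) / s2^1.5
    b2 <- mean((x - m)^4) / s2^2
    Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
    B2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
      ((n - 2) * (n + 5) * (n + 7) * (n + 9))
    W2 <- sqrt(2 * (B2 - 1)) - 1
    dl <- 1 / sqrt(log(sqrt(W2)))
    al <- sqrt(2 / (W2 - 1))
    Zg1 <- dl * log(Y / al + sqrt((Y / al)^2 + 1))
    Eb2 <- 3 * (n - 1) / (n + 1)
    Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
    std <- (b2 - Eb2) / sqrt(Vb2)
    sB1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
      sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
    A <- 6 + 8 / sB1 * (2 / sB1 + sqrt(1 + 4 / sB1^2))
    Zb2 <- ((1 - 2 / (9 * A)) -
              ((1 - 2 / A) / (1 + std * sqrt(2 / (A - 4))))^(1 / 3)) /
      sqrt(2 / (9 * A))
    Zg1^2 + Zb2^2
  }
  set.seed(19)
  x <- rnorm(100)
  r2 <- dagostino_pearson(x)
  expect_equal(r2$k2, oracle_k2(x), tolerance = 1e-9)
  expect_equal(r2$p_value, stats::pchisq(r2$k2, 2, lower.tail = FALSE))
  expect_error(dagostino_pearson(rep(1, 50)), "zero-variance")
  expect_warning(dagostino_pearson(rnorm(15)), "validity floor")
})

test_that("Welch summary test matches the closed form", {
  w0 <- welch_t_from_summary(1, 2, 30, 1, 2, 30)
  expect_equal(w0$t, 0)
  expect_equal(w0$p_value, 1)

  w <- welch_t_from_summary(1, 1, 10, 0, 1, 10)
  expect_equal(w$t, sqrt(5), tolerance = 1e-9)
  expect_equal(round(w$t, 4), 2.2361)
  expect_equal(w$df, 18)
  expect_equal(round(w$p_value, 4), 0.0382)

  # doubling the mean difference doubles t
  w2 <- welch_t_from_summary(2, 1, 10, 0, 1, 10)
  expect_equal(w2$t, 2 * w$t, tolerance = 1e-12)

  # agreement with a raw-data Welch oracle via summaries
  set.seed(20)
  x <- rnorm(25, 0.4, 1.3); y <- rnorm(31, 0, 0.8)
  ws <- welch_t_from_summary(mean(x), sd(x), 25, mean(y), sd(y), 31)
  wt <- stats::t.test(x, y)
  expect_equal(ws$t, unname(wt$statistic), tolerance = 1e-9)
  expect_equal(ws$df, unname(wt$parameter), tolerance = 1e-9)
  expect_equal(ws$p_value, wt$p.value, tolerance = 1e-9)
  expect_error(welch_t_from_summary(1, 0, 5, 1, 0, 5), "both variances")
})

test_that("resolution test against the reference distributions", {
  tab <- reference_distributions("PDvsControl")
  expect_equal(tab$mean[tab$parameter == "stride_s"], 0.040)
  expect_equal(tab$sd[tab$parameter == "double_support_s"], 0.035)
  tab2 <- reference_distributions("ONvsOFF")
  expect_equal(tab2$mean[tab2$parameter == "cadence_spm"], 3.5)

  # bias distribution equal to the reference: p = 1
  ref <- list(parameter = "stride_s", mean = 0.01, sd = 0.02)
  set.seed(21)
  d <- rnorm(200, 0.01, 0.02)
  r <- resolution_test(d, list(parameter = "stride_s", mean = mean(d),
                               sd = sd(d)), ref_n = 200L)
  expect_equal(r$t, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)

  # a tight bias against the broad stride-duration reference: significant
  d2 <- rnorm(685, 0.003, 0.015)
  ref_row <- tab[tab$parameter == "stride_s", ]
  r2 <- resolution_test(d2, as.list(ref_row), ref_n = 100L)
  oracle <- welch_t_from_summary(mean(d2), sd(d2), 685, 0.040, 0.126, 100)
  expect_equal(r2$p_value, oracle$p_value, tolerance = 1e-12)
  expect_lt(r2$p_value, 0.05)

  # inflating the reference SD drives p monotonically to 1
  ps <- vapply(c(1, 10, 100), function(k)
    resolution_test(d2, list(parameter = "x", mean = 0.04,
                             sd = 0.126 * k), 100L)$p_value, numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_gt(ps[3], 0.9)
})

test_that("MAE and the Linear Fit Method match their oracles", {
  w <- seq(0, 60, length.out = 101)
  expect_equal(mae(w, w), 0)
  expect_equal(mae(w, w + 2), 2)
  set.seed(22)
  a <- rnorm(101); b <- rnorm(101)
  expect_equal(mae(a, b), sum(abs(b - a)) / 101, tolerance = 1e-12)
  expect_error(mae(a, b[1:50]), "mismatch")

  lf <- linear_fit_method(w, w)
  expect_equal(c(lf$alpha1, lf$alpha0, lf$r_squared), c(1, 0, 1))
  lf2 <- linear_fit_method(w, 2 * w + 3)
  expect_equal(c(lf2$alpha1, lf2$alpha0, lf2$r_squared), c(2, 3, 1),
               tolerance = 1e-12)
  # seeded noisy pair equals the closed-form OLS oracle
  r <- sin(seq(0, 2 * pi, length.out = 101)) * 20
  s <- 1.3 * r - 2 + rnorm(101, 0, 3)
  lf3 <- linear_fit_method(r, s)
  Sxx <- sum((r - mean(r))^2)
  a1 <- sum((r - mean(r)) * (s - mean(s))) / Sxx
  expect_equal(lf3$alpha1, a1, tolerance = 1e-12)
  expect_equal(lf3$alpha0, mean(s) - a1 * mean(r), tolerance = 1e-12)
  expect_equal(lf3$r_squared, cor(r, s)^2, tolerance = 1e-12)
  expect_equal(lf3$mae, mean(abs(s - r)), tolerance = 1e-12)
  expect_error(linear_fit_method(rep(1, 101), r), "zero-variance")

  # any affine transform of the reference returns exactly its coefficients
  set.seed(23)
  for (i in 1:10) {
    a1 <- runif(1, -2, 2); a0 <- runif(1, -10, 10)
    lf4 <- linear_fit_method(r, a1 * r + a0)
    expect_equal(c(lf4$alpha1, lf4$alpha0), c(a1, a0), tolerance = 1e-9)
    expect_equal(lf4$r_squared, 1, tolerance = 1e-9)
  }
})

test_that("group aggregation reproduces the published summary statistics", {
  tab <- lfm_reference_table()
  expect_equal(nrow(tab), 22L)
  low <- aggregate_lfm(tab[tab$grp == "lower", ], "lower")
  up <- aggregate_lfm(tab[tab$grp == "upper", ], "upper")
  expect_equal(low$alpha1_mean, 0.699, tolerance = 0.005)
  expect_equal(low$alpha0_mean, 2.606, tolerance = 0.005)
  expect_equal(low$alpha1_loa_halfwidth, 0.685, tolerance = 0.005)
  expect_equal(low$alpha0_loa_halfwidth, 4.046, tolerance = 0.005)
  expect_equal(up$alpha1_mean, 0.671, tolerance = 0.005)
  expect_equal(up$alpha0_mean, 6.79, tolerance = 0.005)
  expect_equal(up$alpha1_loa_halfwidth, 0.346, tolerance = 0.005)
  expect_equal(up$alpha0_loa_halfwidth, 8.229, tolerance = 0.005)
  # LoA half-width is exactly 1.96 x population SD
  expect_equal(low$alpha1_loa_halfwidth / low$alpha1_sd, 1.96)
  # identical values aggregate to zero spread
  same <- data.frame(alpha1 = rep(0.8, 4), alpha0 = rep(-2, 4),
                     r_squared = rep(0.9, 4), mae = rep(1, 4))
  agg <- aggregate_lfm(same, "lower")
  expect_equal(agg$alpha1_sd, 0)
  expect_equal(agg$alpha0_loa_halfwidth, 0)
  expect_error(aggregate_lfm(data.frame()), "empty")
})

test_that("validity bands follow the R-squared thresholds", {
  expect_equal(classify_validity(0.781), "very high")
  expect_equal(classify_validity(0.76), "very high")
  expect_equal(classify_validity(0.75), "fair-to-high")   # boundary down
  expect_equal(classify_validity(0.40), "fair-to-high")   # boundary in
  expect_equal(classify_validity(0.39), "low")
  expect_error(classify_validity(1.2), "0, 1")
})
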
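# Method-agreement statistics: Bland-Altman with confidence intervals,
# D'Agostino-Pearson normality omnibus, Welch tests (raw or summary form)
# against pooled reference difference distributions, mean absolute error,
# the Linear Fit Method for waveform similarity, and its group aggregation.

#' Bland-Altman agreement analysis
#'
#' Differences d = x - y; bias = mean(d); limits of agreement
#' bias +- 1.96 * SD(d) (sample SD, n-1). 95% CIs: bias +-
#' t(0.975, n-1) * SD / sqrt(n); each limit +- t(0.975, n-1) * SD *
#' sqrt(3/n) (the standard large-sample approximation for an LoA standard
#' error).
#'
#' @param x,y paired measurements by the two methods (equal length, n >= 3).
#' @return object of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_lower`, `loa_upper`, and `ci_bias`, `ci_loa_lower`,
#'   `ci_loa_upper` (each `c(lower, upper)`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  n <- length(x)
  if (n < 3L) stop("sample-size error: need n >= 3")
  d <- x - y
  bias <- mean(d)
  s <- stats::sd(d)
  tq <- stats::qt(0.975, n - 1)
  se_bias <- s / sqrt(n)
  se_loa <- s * sqrt(3 / n)
  loa <- bias + c(-1.96, 1.96) * s
  structure(list(n = n, bias = bias, sd_diff = s,
                 loa_lower = loa[1], loa_upper = loa[2],
                 ci_bias = bias + c(-1, 1) * tq * se_bias,
                 ci_loa_lower = loa[1] + c(-1, 1) * tq * se_loa,
                 ci_loa_upper = loa[2] + c(-1, 1) * tq * se_loa),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> n=%d bias=%.4f [%.4f, %.4f] LoA=[%.4f, %.4f]\n",
              x$n, x$bias, x$ci_bias[1], x$ci_bias[2],
              x$loa_lower, x$loa_upper))
  invisible(x)
}

#' Difference-versus-mean plot table
#'
#' @param x,y paired measurements.
#' @return data.frame with columns `mean` = (x+y)/2 and `difference` = x-y.
#' @export
mean_vs_diff_points <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  data.frame(mean = (x + y) / 2, difference = x - y)
}

#' D'Agostino-Pearson omnibus normality test
#'
#' K2 = Z1(sqrt(b1))^2 + Z2(b2)^2 combining the transformed sample skewness
#' (D'Agostino's Z via the Johnson SU approximation) and kurtosis
#' (Anscombe-Glynn Z); K2 is referred to chi-squared with 2 df.
#'
#' @param d numeric sample; the standard validity floor is n >= 20
#'   (a warning is issued below).
#' @return object of class `dagostino_pearson`: `k2`, `p_value`, `n`,
#'   `z_skewness`, `z_kurtosis`.
#' @export
dagostino_pearson <- function(d) {
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 8L) stop("need n >= 8")
  if (n < 20L) warning("D'Agostino-Pearson below its validity floor (n < 20)")
  if (stats::sd(d) == 0) stop("test undefined for zero-variance sample")
  m <- mean(d)
  m2 <- mean((d - m)^2); m3 <- mean((d - m)^3); m4 <- mean((d - m)^4)
  b1 <- m3 / m2^1.5                       # sample skewness g1
  b2 <- m4 / m2^2                         # sample kurtosis g2 + 3
  # D'Agostino (1970) skewness transform
  Y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zs <- if (b1 == 0) 0 else delta * asinh(Y / alpha)
  # Anscombe-Glynn (1983) kurtosis transform
  Eb2 <- 3 * (n - 1) / (n + 1)
  Vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(Vb2)
  sqb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqb1 * (2 / sqb1 + sqrt(1 + 4 / sqb1^2))
  Zk <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  k2 <- Zs^2 + Zk^2
  structure(list(k2 = k2, p_value = stats::pchisq(k2, 2, lower.tail = FALSE),
                 n = n, z_skewness = Zs, z_kurtosis = Zk),
            class = "dagostino_pearson")
}

#' @export
print.dagostino_pearson <- function(x, ...) {
  cat(sprintf("<dagostino_pearson> K2=%.3f p=%.4f (n=%d)\n",
              x$k2, x$p_value, x$n))
  invisible(x)
}

#' Welch's two-sample t-test from summary statistics
#'
#' t = (m1 - m2) / sqrt(s1^2/n1 + s2^2/n2) with Welch-Satterthwaite degrees
#' of freedom and a two-sided p value.
#'
#' @param m1,s1,n1 mean, SD and size of sample 1.
#' @param m2,s2,n2 mean, SD and size of sample 2.
#' @return object of class `welch_test`: `t`, `df`, `p_value`.
#' @export
welch_t_from_summary <- function(m1, s1, n1, m2, s2, n2) {
  if (n1 < 2L || n2 < 2L) stop("need n >= 2 in both samples")
  if (s1 < 0 || s2 < 0) stop("SDs must be non-negative")
  v1 <- s1^2 / n1; v2 <- s2^2 / n2
  if (v1 + v2 == 0) stop("undefined: both variances are zero")
  t <- (m1 - m2) / sqrt(v1 + v2)
  df <- (v1 + v2)^2 / (v1^2 / (n1 - 1) + v2^2 / (n2 - 1))
  structure(list(t = t, df = df,
                 p_value = 2 * stats::pt(abs(t), df, lower.tail = FALSE)),
            class = "welch_test")
}

#' @export
print.welch_test <- function(x, ...) {
  cat(sprintf("<welch_test> t=%.4f df=%.2f p=%.4g\n", x$t, x$df, x$p_value))
  invisible(x)
}

#' Pooled reference difference distributions
#'
#' Published absolute difference distributions (mean +- SD) between
#' Parkinson's patients and healthy controls (`PDvsControl`) and between ON
#' and OFF medication states (`ONvsOFF`), per gait parameter, used to judge
#' whether a system's bias is small against clinically meaningful
#' differences.
#'
#' @param group `"PDvsControl"` or `"ONvsOFF"`.
#' @return data.frame with columns `parameter`, `group`, `mean`, `sd`,
#'   `unit`.
#' @export
reference_distributions <- function(group = c("PDvsControl", "ONvsOFF")) {
  group <- match.arg(group)
  tab <- data.frame(
    parameter = c("stride_s", "stance_s", "swing_s", "double_support_s",
                  "cadence_spm", "speed_mps", "length_m", "width_m"),
    unit = c("s", "s", "s", "s", "strides/min", "m/s", "m", "m"),
    pd_mean = c(0.040, 0.044, 0.009, 0.253, 4.000, 0.160, 0.210, 0.008),
    pd_sd   = c(0.126, 0.093, 0.273, 0.035, 16.101, 0.325, 0.292, 0.031),
    onoff_mean = c(0.030, 0.032, 0.007, 0.164, 3.500, 0.060, 0.140, 0.001),
    onoff_sd   = c(0.156, 0.094, 0.053, 0.026, 13.086, 0.030, 0.292, 0.038))
  if (group == "PDvsControl")
    data.frame(parameter = tab$parameter, group = group,
               mean = tab$pd_mean, sd = tab$pd_sd, unit = tab$unit)
  else
    data.frame(parameter = tab$parameter, group = group,
               mean = tab$onoff_mean, sd = tab$onoff_sd, unit = tab$unit)
}

#' Resolution test of a bias distribution against a reference
#'
#' Welch's t-test of the per-cycle difference distribution of one gait
#' parameter against a pooled reference difference distribution. The
#' reference sample size is not published and must be supplied.
#'
#' @param bias_values per-cycle differences for one parameter.
#' @param ref one row of [reference_distributions()] (fields `mean`, `sd`).
#' @param ref_n assumed reference sample size (config input; reported back).
#' @return a `welch_test` with fields `ref_n` and `parameter` attached.
#' @export
resolution_test <- function(bias_values, ref, ref_n = 100L) {
  bias_values <- bias_values[is.finite(bias_values)]
  out <- welch_t_from_summary(mean(bias_values), stats::sd(bias_values),
                              length(bias_values), ref$mean, ref$sd, ref_n)
  out$ref_n <- ref_n
  out$parameter <- ref$parameter %||% ""
  out
}

#' Mean absolute error between two normalized waveforms
#'
#' @param reference,test [normalize_gait_cycle()] results (101 points,
#'   same DoF/side) or bare numeric vectors of equal length.
#' @return mean of |test - reference| in the waveform's units.
#' @export
mae <- function(reference, test) {
  r <- if (inherits(reference, "normalized_waveform")) reference$values else reference
  s <- if (inherits(test, "normalized_waveform")) test$values else test
  if (length(r) != length(s)) stop("waveform length mismatch")
  mean(abs(s - r))
}

#' Linear Fit Method waveform similarity
#'
#' Ordinary least squares of the test waveform on the reference (criterion)
#' waveform: test ~ alpha1 * reference + alpha0. R^2 is the squared Pearson
#' correlation; the mean absolute error is attached.
#'
#' @param reference,test [normalize_gait_cycle()] results or numeric
#'   vectors of equal length; the reference must have positive variance.
#' @return object of class `lfm_result`: `alpha1`, `alpha0`, `r_squared`,
#'   `mae`, plus `dof` and `side` when available.
#' @export
linear_fit_method <- function(reference, test) {
  r <- if (inherits(reference, "normalized_waveform")) reference$values else reference
  s <- if (inherits(test, "normalized_waveform")) test$values else test
  if (length(r) != length(s)) stop("waveform length mismatch")
  vr <- stats::var(r)
  if (vr == 0) stop("undefined: zero-variance reference waveform")
  a1 <- stats::cov(r, s) / vr
  a0 <- mean(s) - a1 * mean(r)
  vs <- stats::var(s)
  r2 <- if (vs == 0) 1 else stats::cor(r, s)^2
  structure(list(alpha1 = a1, alpha0 = a0, r_squared = r2,
                 mae = mean(abs(s - r)),
                 dof = if (inherits(reference, "normalized_waveform"))
                   reference$dof else "",
                 side = if (inherits(reference, "normalized_waveform"))
                   reference$side else ""),
            class = "lfm_result")
}

#' @export
print.lfm_result <- function(x, ...) {
  cat(sprintf("<lfm_result> alpha1=%.3f alpha0=%.3f R2=%.3f MAE=%.3f\n",
              x$alpha1, x$alpha0, x$r_squared, x$mae))
  invisible(x)
}

#' Aggregate Linear Fit Method results over a DoF group
#'
#' Group summaries as reported for validation: `alpha1` aggregated on raw
#' values and `alpha0` on absolute values, each with the population SD
#' (divisor n) and limits of agreement +- 1.96 * SD; `r_squared` and `mae`
#' aggregated as means only.
#'
#' @param results list of `lfm_result`s or a data.frame with columns
#'   `alpha1`, `alpha0`, `r_squared`, `mae`.
#' @param group label (`"lower"` or `"upper"` limb group).
#' @return object of class `lfm_aggregate`: per-coefficient `mean`, `sd`
#'   (population), `loa_halfwidth`; `r_squared_mean`, `mae_mean`; `n`;
#'   `validity` from [classify_validity()].
#' @export
aggregate_lfm <- function(results, group = "lower") {
  df <- if (is.data.frame(results)) results else
    do.call(rbind, lapply(results, function(r)
      data.frame(alpha1 = r$alpha1, alpha0 = r$alpha0,
                 r_squared = r$r_squared, mae = r$mae)))
  if (is.null(df) || !nrow(df)) stop("empty group")
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  a1_m <- mean(df$alpha1); a1_s <- pop_sd(df$alpha1)
  a0 <- abs(df$alpha0)
  a0_m <- mean(a0); a0_s <- pop_sd(a0)
  r2_m <- mean(df$r_squared)
  structure(list(group = group, n = nrow(df),
                 alpha1_mean = a1_m, alpha1_sd = a1_s,
                 alpha1_loa_halfwidth = 1.96 * a1_s,
                 alpha0_mean = a0_m, alpha0_sd = a0_s,
                 alpha0_loa_halfwidth = 1.96 * a0_s,
                 r_squared_mean = r2_m, mae_mean = mean(df$mae),
                 validity = classify_validity(r2_m)),
            class = "lfm_aggregate")
}

#' @export
print.lfm_aggregate <- function(x, ...) {
  cat(sprintf(
    "<lfm_aggregate> %s (n=%d): a1 %.3f+-%.3f (LoA +-%.3f), |a0| %.3f (LoA +-%.3f), R2 %.3f (%s), MAE %.3f\n",
    x$group, x$n, x$alpha1_mean, x$alpha1_sd, x$alpha1_loa_halfwidth,
    x$alpha0_mean, x$alpha0_loa_halfwidth, x$r_squared_mean, x$validity,
    x$mae_mean))
  invisible(x)
}

#' Concurrent-validity band of a mean R^2
#'
#' Very high above 0.75, fair-to-high for 0.40-0.75 (inclusive of both
#' boundaries), low below 0.40.
#'
#' @param r2 mean coefficient of determination, in `[0, 1]`.
#' @return `"very high"`, `"fair-to-high"` or `"low"`.
#' @export
classify_validity <- function(r2) {
  if (!is.finite(r2) || r2 < 0 || r2 > 1) stop("r2 must be in [0, 1]")
  if (r2 > 0.75) "very high" else if (r2 >= 0.40) "fair-to-high" else "low"
}

#' Published per-DoF Linear Fit Method reference values
#'
#' The per-DoF LFM outcome fixture comparing inertial full-body kinematics
#' with the optoelectronic criterion: `alpha1`, `alpha0` (degrees), `r_squared`
#' and `mae` (degrees) for the 11 validated DoF on each body side. Lower
#' group: 5 lower-limb DoF x 2 sides; upper group: 6 upper-extremity DoF x
#' 2 sides.
#'
#' @return data.frame with columns `dof`, `side`, `grp`, `alpha1`,
#'   `alpha0`, `r_squared`, `mae`.
#' @export
lfm_reference_table <- function() {
  dof <- c("hip_flexion", "hip_adduction", "hip_rotation", "knee_extension",
           "ankle_dorsiflexion", "arm_flexion", "arm_adduction",
           "arm_rotation", "elbow_flexion", "pronation", "wrist_flexion")
  grp <- c(rep("lower", 5), rep("upper", 6))
  a1_l <- c(0.910, 0.481, 0.258, 1.117, 0.816, 0.395, 0.653, 0.622, 0.668,
            0.933, 0.593)
  a1_r <- c(0.903, 0.487, 0.035, 1.144, 0.841, 0.478, 0.611, 0.527, 0.810,
            1.040, 0.725)
  a0_l <- c(-1.716, -0.467, -6.486, 4.331, 0.051, 7.335, -11.419, -3.013,
            6.777, -8.582, 2.687)
  a0_r <- c(-3.101, 0.948, -5.370, -2.399, 1.187, -11.133, 9.456, -0.108,
            7.735, 13.084, 0.122)
  r2_l <- c(0.919, 0.737, 0.514, 0.957, 0.860, 0.798, 0.875, 0.770, 0.868,
            0.685, 0.524)
  r2_r <- c(0.913, 0.561, 0.608, 0.950, 0.789, 0.843, 0.856, 0.683, 0.887,
            0.678, 0.534)
  mae_l <- c(2.296, 3.297, 3.511, 2.950, 2.924, 2.990, 2.170, 2.339, 1.830,
             2.368, 2.342)
  mae_r <- c(2.504, 3.630, 3.901, 2.957, 2.946, 2.713, 2.248, 2.504, 2.118,
             2.615, 1.944)
  rbind(data.frame(dof = dof, side = "left", grp = grp, alpha1 = a1_l,
                   alpha0 = a0_l, r_squared = r2_l, mae = mae_l),
        data.frame(dof = dof, side = "right", grp = grp, alpha1 = a1_r,
                   alpha0 = a0_r, r_squared = r2_r, mae = mae_r))
}
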
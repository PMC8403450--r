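# Inverse kinematics: per-frame weighted least squares solved by damped
# Gauss-Newton (Levenberg-Marquardt style) with numerical Jacobians,
# warm-started from the previous frame. The same solver core serves both
# the marker-residual (optoelectronic) and orientation-residual (IMU)
# objectives.

IK_MAX_ITER <- 100L
IK_STEP_TOL <- 1e-10

# residual_fun(theta) -> numeric residual vector
solve_frame <- function(theta0, residual_fun, max_iter = IK_MAX_ITER,
                        step_tol = IK_STEP_TOL) {
  theta <- theta0
  r <- residual_fun(theta)
  obj <- sum(r^2)
  lambda <- 1e-3
  n <- length(theta)
  eps <- 1e-7
  unidentifiable <- rep(FALSE, n)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    J <- matrix(0, length(r), n)
    for (k in seq_len(n)) {
      tp <- theta; tp[k] <- tp[k] + eps
      J[, k] <- (residual_fun(tp) - r) / eps
    }
    cn <- sqrt(colSums(J^2))
    unidentifiable <- cn < 1e-10
    use <- !unidentifiable
    if (!any(use)) break
    Ju <- J[, use, drop = FALSE]
    g <- crossprod(Ju, r)
    H <- crossprod(Ju)
    improved <- FALSE
    for (try in 1:8) {
      step <- tryCatch(
        solve(H + lambda * diag(diag(H) + 1e-12, ncol(H)), g),
        error = function(e) NULL)
      if (!is.null(step)) {
        cand <- theta
        cand[use] <- cand[use] - step
        rc <- residual_fun(cand)
        oc <- sum(rc^2)
        if (is.finite(oc) && oc <= obj) {   # objective never increases
          moved <- max(abs(cand - theta))
          theta <- cand; r <- rc
          improved <- TRUE
          delta <- obj - oc
          obj <- oc
          lambda <- max(lambda / 3, 1e-12)
          if (moved < step_tol || delta < step_tol^2) converged <- TRUE
          break
        }
      }
      lambda <- lambda * 10
    }
    if (!improved) { converged <- obj < 1e-18 || it > 1; break }
    if (converged) break
  }
  list(theta = theta, objective = obj, converged = converged,
       unidentifiable = unidentifiable)
}

#' Marker-driven inverse kinematics
#'
#' Per frame, finds the joint angles minimising the weighted sum of squared
#' distances between observed and model-determined marker positions,
#' \eqn{\sum_i w_i \| m_i^{obs} - m_i^{model}(\theta) \|^2}. Observations
#' must already be expressed in the model (pelvis) frame (see
#' [express_in_pelvis()]); the root is held at the identity pose.
#'
#' @param model a [kinematic_model()].
#' @param observed a [marker_set()] in pelvis coordinates; labels must match
#'   model marker names (extra markers are ignored, occluded samples are
#'   skipped).
#' @param weights optional named non-negative weights per marker
#'   (default 1). Markers with weight 0 are excluded.
#' @param theta0 optional initial pose for the first frame.
#' @return a [pose_trajectory()]; frames where the solver failed to
#'   converge are flagged and carry the previous frame's angles. DoF left
#'   unidentifiable by the observed marker set are reported via the
#'   `unidentifiable` attribute.
#' @export
ik_markers <- function(model, observed, weights = NULL, theta0 = NULL) {
  labs <- intersect(rownames_model_markers(model), names(observed$trajectories))
  if (length(labs) < 3L)
    stop("need at least 3 model markers observed")
  w <- stats::setNames(rep(1, length(labs)), labs)
  if (!is.null(weights)) {
    if (any(weights < 0)) stop("weights must be non-negative")
    w[intersect(names(weights), labs)] <- weights[intersect(names(weights), labs)]
  }
  labs <- labs[w[labs] > 0]
  sw <- sqrt(w[labs])
  obs <- lapply(labs, function(l) observed$trajectories[[l]]$values)
  nfr <- observed$n
  ndof <- length(model$dof_names)
  theta <- theta0 %||% rep(0, ndof)
  angles <- matrix(NA_real_, nfr, ndof, dimnames = list(NULL, model$dof_names))
  flags <- rep(FALSE, nfr)
  unident <- rep(FALSE, ndof)
  gapmat <- observed$gaps[, labs, drop = FALSE]
  for (fr in seq_len(nfr)) {
    keep <- !gapmat[fr, ]
    target <- do.call(rbind, lapply(which(keep), function(k) obs[[k]][fr, ]))
    lab_fr <- labs[keep]; sw_fr <- sw[keep]
    resid <- function(th) {
      fk <- forward_kinematics(model, stats::setNames(th, model$dof_names),
                               orientations = FALSE)
      d <- (fk$markers[lab_fr, , drop = FALSE] - target) * sw_fr
      as.numeric(d)
    }
    sol <- solve_frame(theta, resid)
    unident <- unident | sol$unidentifiable
    if (sol$converged || fr == 1L) {
      theta <- sol$theta
      angles[fr, ] <- theta
      flags[fr] <- !sol$converged
    } else {                       # carry previous frame, flag
      angles[fr, ] <- theta
      flags[fr] <- TRUE
    }
  }
  if (any(flags))
    warning(sum(flags), " frame(s) did not converge; previous pose carried")
  out <- pose_trajectory(observed$t0 + (seq_len(nfr) - 1L) / observed$fs,
                         angles, flags = flags)
  attr(out, "unidentifiable") <- stats::setNames(unident, model$dof_names)
  out
}

rownames_model_markers <- function(model)
  unlist(lapply(model$segments, function(s) names(s$markers)), use.names = FALSE)

#' Orientation-driven inverse kinematics
#'
#' Per frame, finds the joint angles minimising the sum of squared geodesic
#' angles between observed segment (IMU) orientations and the model's IMU
#' frames. Observed orientations are interpreted in the model root frame
#' (sensor-to-pelvis); the residual is the rotation vector of
#' \eqn{q_{model}^{-1} \otimes q_{obs}}, whose norm is the geodesic angle.
#'
#' @param model a [kinematic_model()].
#' @param observed named list of `quaternion_series`, one per instrumented
#'   segment; all series must share an identical time grid.
#' @param theta0 optional initial pose.
#' @return a [pose_trajectory()] (see [ik_markers()] for flag semantics).
#' @export
ik_orientations <- function(model, observed, theta0 = NULL) {
  segs <- names(observed)
  bad <- setdiff(segs, names(model$segments))
  if (length(bad)) stop("configuration error: unmapped sensor id ", bad[1])
  tm <- observed[[1]]$timestamps
  for (s in observed)
    if (length(s$timestamps) != length(tm) || any(abs(s$timestamps - tm) > 1e-9))
      stop("alignment error: observed orientation streams must share a grid")
  imu_local <- lapply(segs, function(nm) model$segments[[nm]]$imu)
  names(imu_local) <- segs
  ndof <- length(model$dof_names)
  theta <- theta0 %||% rep(0, ndof)
  nfr <- length(tm)
  angles <- matrix(NA_real_, nfr, ndof, dimnames = list(NULL, model$dof_names))
  flags <- rep(FALSE, nfr)
  R_imu <- lapply(imu_local, quat_to_matrix)
  for (fr in seq_len(nfr)) {
    R_obs <- lapply(segs, function(nm)
      quat_to_matrix(observed[[nm]]$quaternions[fr, ]))
    resid <- function(th) {
      fk <- forward_kinematics(model, stats::setNames(th, model$dof_names),
                               orientations = FALSE)
      out <- numeric(3L * length(segs))
      for (k in seq_along(segs)) {
        Rm <- fk$segment_rotation[[segs[k]]] %*% R_imu[[k]]
        out[(3L * k - 2L):(3L * k)] <-
          quat_to_rotvec(quat_from_matrix(crossprod(Rm, R_obs[[k]])))
      }
      out
    }
    sol <- solve_frame(theta, resid)
    theta <- sol$theta
    angles[fr, ] <- theta
    flags[fr] <- !sol$converged && fr > 1L
  }
  if (any(flags))
    warning(sum(flags), " frame(s) did not converge; previous pose carried")
  pose_trajectory(tm, angles, flags = flags)
}
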
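# Configurable rigid-segment kinematic chain.
#
# Coordinate convention (world and pelvis): x = right, y = forward
# (direction of travel), z = up. The segment graph is a tree rooted at the
# pelvis; each non-root segment attaches to its parent at a joint-centre
# offset expressed in the parent frame and rotates about 1-3 Cardan axes.
# Joint angles are intrinsic Cardan-Euler angles in the segment's stated
# sequence; per-DoF signs let clinically positive directions (flexion
# positive, dorsiflexion positive) map onto the raw axis rotations.

axis_index <- function(ch) match(toupper(ch), c("X", "Y", "Z"))

rot_elem <- function(axis, theta) {
  c <- cos(theta); s <- sin(theta)
  switch(axis,
         matrix(c(1, 0, 0, 0, c, -s, 0, s, c), 3, byrow = TRUE),
         matrix(c(c, 0, s, 0, 1, 0, -s, 0, c), 3, byrow = TRUE),
         matrix(c(c, -s, 0, s, c, 0, 0, 0, 1), 3, byrow = TRUE))
}

#' Compose a rotation from Cardan angles
#'
#' Intrinsic elemental rotations applied in the order of `sequence`.
#'
#' @param angles numeric vector of 1-3 angles, radians.
#' @param sequence axis string such as `"XYZ"`, `"XZY"` or `"X"`.
#' @return 3 x 3 rotation matrix.
#' @export
cardan_matrix <- function(angles, sequence) {
  ax <- vapply(strsplit(sequence, "")[[1]], axis_index, integer(1))
  if (length(ax) != length(angles)) stop("angle count must match sequence")
  R <- diag(3)
  for (i in seq_along(ax)) R <- R %*% rot_elem(ax[i], angles[i])
  R
}

#' Extract Cardan angles from a rotation
#'
#' Decomposes a rotation into three intrinsic elemental rotations about the
#' distinct axes of `sequence`, such that recomposition in the stated order
#' reproduces the input. When the middle angle is within 0.5 degrees of
#' gimbal lock (+-90 deg) the result carries attribute `gimbal_warning`.
#'
#' @param rotation unit quaternion (length 4) or 3 x 3 rotation matrix.
#' @param sequence three-letter axis permutation, e.g. `"XYZ"`, `"XZY"`.
#' @return numeric length-3 vector of angles, radians.
#' @export
cardan_angles <- function(rotation, sequence) {
  R <- if (is.matrix(rotation)) rotation else quat_to_matrix(rotation)
  ax <- vapply(strsplit(sequence, "")[[1]], axis_index, integer(1))
  if (length(ax) != 3L || anyDuplicated(ax))
    stop("sequence must be a permutation of three distinct axes")
  i <- ax[1]; j <- ax[2]; k <- ax[3]
  cyclic <- (j - i) %% 3L == 1L
  s <- if (cyclic) 1 else -1
  sin2 <- max(-1, min(1, s * R[i, k]))
  th2 <- asin(sin2)
  th1 <- atan2(-s * R[j, k], R[k, k])
  th3 <- atan2(-s * R[i, j], R[i, i])
  out <- c(th1, th2, th3)
  if (abs(abs(th2) - pi / 2) < 0.5 * pi / 180)
    attr(out, "gimbal_warning") <- TRUE
  out
}

#' Define a rigid-segment kinematic model
#'
#' @param segments named list; each element is a list with fields
#'   \describe{
#'     \item{parent}{parent segment name, or `NA` for the root.}
#'     \item{offset}{joint-centre position in the parent frame, meters.}
#'     \item{sequence}{Cardan axis string (`""` for a rigid attachment).}
#'     \item{dof}{DoF labels, one per sequence axis.}
#'     \item{signs}{optional +-1 per DoF mapping clinical sign onto the raw
#'       axis rotation (default all +1).}
#'     \item{markers}{named list of local marker positions, meters.}
#'     \item{imu}{optional local IMU frame as a unit quaternion
#'       (default identity).}
#'   }
#' @param reference_height stature the geometry was authored for, meters.
#' @return object of class `kinematic_model`.
#' @export
kinematic_model <- function(segments, reference_height = 1.70) {
  nm <- names(segments)
  if (is.null(nm) || anyDuplicated(nm)) stop("segments must be uniquely named")
  roots <- nm[vapply(segments, function(s) is.na(s$parent %||% NA), logical(1))]
  if (length(roots) != 1L) stop("exactly one root segment is required")
  seen <- character(0)
  for (i in seq_along(segments)) {
    s <- segments[[i]]
    if (!is.na(s$parent %||% NA) && !(s$parent %in% seen))
      stop("segments must be listed parents-first; bad parent for ", nm[i])
    seen <- c(seen, nm[i])
    seq_i <- s$sequence %||% ""
    ndof <- nchar(seq_i)
    if (ndof > 0 && length(s$dof %||% character(0)) != ndof)
      stop("segment ", nm[i], ": dof labels must match sequence length")
    if (is.null(s$signs)) segments[[i]]$signs <- rep(1, ndof)
    if (is.null(s$imu)) segments[[i]]$imu <- c(1, 0, 0, 0)
    if (is.null(s$markers)) segments[[i]]$markers <- list()
    if (is.null(s$offset)) segments[[i]]$offset <- c(0, 0, 0)
    segments[[i]]$marker_mat <-
      if (length(segments[[i]]$markers)) do.call(rbind, segments[[i]]$markers)
      else NULL
    segments[[i]]$axes <-
      if (ndof > 0) vapply(strsplit(seq_i, "")[[1]], axis_index, integer(1))
      else integer(0)
  }
  dof <- unlist(lapply(segments, function(s) s$dof), use.names = FALSE)
  if (anyDuplicated(dof)) stop("DoF labels must be unique")
  structure(list(segments = segments, root = roots,
                 dof_names = dof %||% character(0),
                 reference_height = reference_height),
            class = "kinematic_model")
}

#' @export
print.kinematic_model <- function(x, ...) {
  cat(sprintf("<kinematic_model> %d segments, %d DoF, reference height %.2f m\n",
              length(x$segments), length(x$dof_names), x$reference_height))
  invisible(x)
}

#' Scale a model to a participant's stature
#'
#' All joint-centre offsets and local marker positions are multiplied by
#' `height / reference_height`; DoF definitions are untouched.
#'
#' @param model a [kinematic_model()].
#' @param height participant stature, meters (> 0).
#' @return scaled model (its `reference_height` becomes `height`, so
#'   rescaling to the same stature is the identity).
#' @export
scale_model <- function(model, height) {
  if (!is.numeric(height) || height <= 0)
    stop("parameter error: height must be positive")
  r <- height / model$reference_height
  for (i in seq_along(model$segments)) {
    model$segments[[i]]$offset <- model$segments[[i]]$offset * r
    model$segments[[i]]$markers <- lapply(model$segments[[i]]$markers,
                                          function(m) m * r)
    if (!is.null(model$segments[[i]]$marker_mat))
      model$segments[[i]]$marker_mat <- model$segments[[i]]$marker_mat * r
  }
  model$reference_height <- height
  model
}

#' Forward kinematics
#'
#' @param model a [kinematic_model()].
#' @param pose named numeric vector supplying one angle (radians, clinical
#'   sign convention) per model DoF.
#' @param root_pos root (pelvis) origin in the world frame, meters.
#' @param root_q root orientation, unit quaternion.
#' @param orientations compute segment orientation quaternions (skippable
#'   for speed inside marker-residual loops).
#' @return list with `markers` (named M x 3 matrix of global positions),
#'   `segment_orientation` (named S x 4 quaternion matrix, or `NULL`) and
#'   `segment_origin` (named S x 3 matrix).
#' @export
forward_kinematics <- function(model, pose, root_pos = c(0, 0, 0),
                               root_q = c(1, 0, 0, 0), orientations = TRUE) {
  missing <- setdiff(model$dof_names, names(pose))
  if (length(missing))
    stop("parameter error: pose is missing DoF ", missing[1])
  segs <- model$segments
  nm <- names(segs)
  nseg <- length(segs)
  Rg <- vector("list", nseg); names(Rg) <- nm
  pos <- matrix(NA_real_, nseg, 3, dimnames = list(nm, NULL))
  root_R <- quat_to_matrix(root_q)
  mk_list <- vector("list", nseg)
  for (i in seq_len(nseg)) {
    s <- segs[[i]]
    if (is.na(s$parent %||% NA)) {
      Rp <- root_R; pp <- root_pos
    } else {
      Rp <- Rg[[s$parent]]; pp <- pos[s$parent, ]
    }
    p_i <- pp + Rp %*% s$offset
    R_i <- Rp
    if (length(s$axes)) {
      ang <- pose[s$dof] * s$signs
      for (k in seq_along(s$axes)) R_i <- R_i %*% rot_elem(s$axes[k], ang[k])
    }
    Rg[[i]] <- R_i; pos[i, ] <- p_i
    if (!is.null(s$marker_mat)) {
      gm <- s$marker_mat %*% t(R_i)
      gm[, 1] <- gm[, 1] + p_i[1]
      gm[, 2] <- gm[, 2] + p_i[2]
      gm[, 3] <- gm[, 3] + p_i[3]
      mk_list[[i]] <- gm
    }
  }
  mk <- do.call(rbind, mk_list[!vapply(mk_list, is.null, logical(1))])
  qs <- if (orientations) t(vapply(Rg, quat_from_matrix, numeric(4))) else NULL
  list(markers = mk, segment_orientation = qs, segment_origin = pos,
       segment_rotation = Rg)
}

#' Built-in gait model
#'
#' A reduced full-body chain for gait validation: pelvis root; per leg a
#' 3-DoF ball-and-socket hip (sequence XYZ: flexion about the right axis,
#' ab/adduction about the forward axis, axial rotation about the vertical),
#' 1-DoF knee and 1-DoF ankle; optionally one 6-DoF arm chain (3-DoF
#' shoulder with sequence XZY, 1-DoF elbow, 1-DoF forearm pronation, 1-DoF
#' wrist). Segment lengths follow standard anthropometric proportions of a
#' 1.70 m reference stature. Flexion and dorsiflexion are positive.
#'
#' @param legs `"both"`, `"left"` or `"right"`.
#' @param arm `"right"`, `"left"` or `"none"`.
#' @param reference_height reference stature, meters.
#' @return a [kinematic_model()].
#' @export
default_model <- function(legs = "both", arm = "right",
                          reference_height = 1.70) {
  legs <- match.arg(legs, c("both", "left", "right"))
  arm <- match.arg(arm, c("right", "left", "none"))
  H <- reference_height
  thigh_l <- 0.245 * H; shank_l <- 0.246 * H; ankle_h <- 0.039 * H
  uarm_l <- 0.186 * H; farm_l <- 0.146 * H
  segs <- list(
    pelvis = list(parent = NA, offset = c(0, 0, 0), sequence = "",
                  dof = character(0),
                  markers = list(LASIS = c(-0.12, 0, 0), RASIS = c(0.12, 0, 0),
                                 LPSIS = c(-0.05, -0.15, 0),
                                 RPSIS = c(0.05, -0.15, 0))))
  add_leg <- function(segs, sd) {
    sx <- if (sd == "L") -1 else 1
    segs[[paste0("thigh_", sd)]] <- list(
      parent = "pelvis", offset = c(sx * 0.09, 0, -0.05),
      sequence = "XYZ",
      dof = paste0(c("hip_flexion_", "hip_adduction_", "hip_rotation_"), sd),
      signs = c(1, -sx, 1),    # adduction positive toward the midline
      markers = stats::setNames(list(c(sx * 0.06, 0.02, -0.12),
                                     c(sx * 0.05, -0.03, -0.22),
                                     c(sx * 0.02, 0.05, -0.31)),
                                paste0("thigh_", sd, "_", 1:3)))
    segs[[paste0("shank_", sd)]] <- list(
      parent = paste0("thigh_", sd), offset = c(0, 0, -thigh_l),
      sequence = "X", dof = paste0("knee_flexion_", sd), signs = -1,
      markers = stats::setNames(list(c(sx * 0.05, 0.01, -0.10),
                                     c(sx * 0.05, -0.03, -0.22),
                                     c(sx * 0.01, 0.04, -0.30)),
                                paste0("shank_", sd, "_", 1:3)))
    segs[[paste0("foot_", sd)]] <- list(
      parent = paste0("shank_", sd), offset = c(0, 0, -shank_l),
      sequence = "X", dof = paste0("ankle_dorsiflexion_", sd), signs = 1,
      markers = stats::setNames(list(c(0, -0.06, -ankle_h),
                                     c(0, 0.19, -ankle_h),
                                     c(sx * 0.05, 0.05, -ankle_h)),
                                paste0(c("heel_", "toe_", "foot_lat_"), sd)))
    segs
  }
  if (legs %in% c("both", "left")) segs <- add_leg(segs, "L")
  if (legs %in% c("both", "right")) segs <- add_leg(segs, "R")
  if (arm != "none") {
    sd <- if (arm == "left") "L" else "R"
    sx <- if (sd == "L") -1 else 1
    segs[[paste0("upperarm_", sd)]] <- list(
      parent = "pelvis", offset = c(sx * 0.19, 0, 0.47),
      sequence = "XZY",
      dof = paste0(c("arm_flexion_", "arm_adduction_", "arm_rotation_"), sd),
      signs = c(1, -sx, 1),
      markers = stats::setNames(list(c(sx * 0.04, 0.02, -0.08),
                                     c(sx * 0.04, -0.02, -0.18),
                                     c(sx * 0.01, 0.04, -0.26)),
                                paste0("uarm_", sd, "_", 1:3)))
    segs[[paste0("forearm_", sd)]] <- list(
      parent = paste0("upperarm_", sd), offset = c(0, 0, -uarm_l),
      sequence = "XZ",
      dof = paste0(c("elbow_flexion_", "pronation_"), sd), signs = c(1, 1),
      markers = stats::setNames(list(c(sx * 0.03, 0.01, -0.07),
                                     c(sx * 0.03, -0.02, -0.15),
                                     c(sx * 0.01, 0.03, -0.22)),
                                paste0("farm_", sd, "_", 1:3)))
    segs[[paste0("hand_", sd)]] <- list(
      parent = paste0("forearm_", sd), offset = c(0, 0, -farm_l),
      sequence = "X", dof = paste0("wrist_flexion_", sd), signs = 1,
      markers = stats::setNames(list(c(0, 0.02, -0.03),
                                     c(sx * 0.03, 0.01, -0.07),
                                     c(0, -0.02, -0.09)),
                                paste0("hand_", sd, "_", 1:3)))
  }
  kinematic_model(segs, reference_height = reference_height)
}

#' Neutral pose (all angles zero) for a model
#' @param model a [kinematic_model()].
#' @return named numeric vector of zeros over the model's DoF.
#' @export
neutral_pose <- function(model)
  stats::setNames(rep(0, length(model$dof_names)), model$dof_names)

#' Joint-angle trajectory container
#'
#' @param time uniform time grid, seconds.
#' @param angles N x D matrix of angles, radians; columns named by DoF.
#' @param flags optional per-frame logical, `TRUE` where the solver did not
#'   converge (angles carried from the previous frame).
#' @return object of class `pose_trajectory`.
#' @export
pose_trajectory <- function(time, angles, flags = NULL) {
  angles <- as.matrix(angles)
  if (length(time) != nrow(angles)) stop("time/angle length mismatch")
  if (any(!is.finite(angles))) stop("angles must be finite")
  structure(list(time = as.numeric(time), angles = angles,
                 labels = colnames(angles),
                 flags = flags %||% rep(FALSE, length(time))),
            class = "pose_trajectory")
}

#' @export
print.pose_trajectory <- function(x, ...) {
  cat(sprintf("<pose_trajectory> %d frames x %d DoF (%d flagged)\n",
              length(x$time), ncol(x$angles), sum(x$flags)))
  invisible(x)
}

#' Time-normalize one gait cycle of an angle series
#'
#' Linear interpolation of the series onto the 0-100% cycle grid (101
#' points) between the cycle's bracketing ipsilateral heel strikes.
#'
#' @param angle a [uniform_series()] (single column) or `pose_trajectory`
#'   column extracted as a series.
#' @param cycle a gait cycle (see [build_cycles()]); only `start` and `end`
#'   times are used.
#' @param dof,side labels attached to the result.
#' @return object of class `normalized_waveform`: fields `values` (length
#'   101), `dof`, `side`.
#' @export
normalize_gait_cycle <- function(angle, cycle, dof = "", side = cycle$side %||% "") {
  tm <- series_time(angle)
  if (cycle$start < tm[1] - 1e-9 || cycle$end > tm[length(tm)] + 1e-9)
    stop("range error: cycle lies outside the series span")
  grid <- seq(cycle$start, cycle$end, length.out = 101L)
  v <- stats::approx(tm, angle$values[, 1], xout = grid, rule = 2,
                     ties = "ordered")$y
  structure(list(values = v, dof = dof, side = side,
                 start = cycle$start, end = cycle$end),
            class = "normalized_waveform")
}

#' @export
print.normalized_waveform <- function(x, ...) {
  cat(sprintf("<normalized_waveform> %s %s: 101 points over [%.3f, %.3f] s\n",
              x$dof, x$side, x$start, x$end))
  invisible(x)
}
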
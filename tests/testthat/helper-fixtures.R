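# Shared helpers for the test suite. Everything is built in code; no
# binary fixtures.

random_unit_quat <- function(n = 1L) {
  q <- matrix(stats::rnorm(4L * n), n)
  q / sqrt(rowSums(q^2))
}

# marker_set from a list of per-frame named marker matrices
marker_set_from_frames <- function(frames, fs = 120, t0 = 0) {
  labs <- rownames(frames[[1L]])
  trajs <- stats::setNames(lapply(labs, function(l)
    uniform_series(t(vapply(frames, function(f) f[l, ], numeric(3))),
                   fs = fs, t0 = t0, label = l)), labs)
  marker_set(trajs)
}

# marker_set generated by a model's own FK over a pose matrix
fk_marker_set <- function(model, poses, fs = 120) {
  frames <- lapply(seq_len(nrow(poses)), function(i)
    forward_kinematics(model, poses[i, ], orientations = FALSE)$markers)
  marker_set_from_frames(frames, fs = fs)
}

# per-segment quaternion_series generated by FK
fk_orientation_streams <- function(model, poses, fs = 120) {
  tm <- (seq_len(nrow(poses)) - 1L) / fs
  qs <- lapply(seq_len(nrow(poses)), function(i)
    forward_kinematics(model, poses[i, ])$segment_orientation)
  segs <- setdiff(names(model$segments), model$root)
  stats::setNames(lapply(segs, function(s)
    quaternion_series(tm, quat_normalize(
      t(vapply(qs, function(q) q[s, ], numeric(4)))))), segs)
}

# smooth random pose matrix over the model's DoF
smooth_poses <- function(model, n, amplitude = 0.3) {
  nd <- length(model$dof_names)
  tt <- seq(0, 1, length.out = n)
  poses <- vapply(seq_len(nd), function(k)
    amplitude * sin(2 * pi * tt + k), numeric(n))
  colnames(poses) <- model$dof_names
  poses
}

# planar one-DoF knee test model: thigh fixed to the root, one hinge
hinge_model <- function() {
  kinematic_model(list(
    pelvis = list(parent = NA, offset = c(0, 0, 0), sequence = "",
                  dof = character(0),
                  markers = list(P1 = c(0.1, 0, 0), P2 = c(-0.1, 0, 0),
                                 P3 = c(0, -0.15, 0))),
    shank = list(parent = "pelvis", offset = c(0, 0, -0.4), sequence = "X",
                 dof = "knee", signs = -1,
                 markers = list(S1 = c(0.05, 0.02, -0.1),
                                S2 = c(-0.04, 0.03, -0.25),
                                S3 = c(0.02, -0.05, -0.35)))))
}
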
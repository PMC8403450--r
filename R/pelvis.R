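# Pelvis anatomical frame and pelvis-centred marker expression.
#
# The pelvis frame is built from the four iliac-spine markers: origin at the
# ASIS midpoint; first axis ("right") along RASIS - LASIS; the plane through
# the ASIS midpoint and the PSIS midpoint defines the forward axis
# (orthogonalised against right); up completes the right-handed triad.
# Returned basis column order: right, forward, up.

#' Pelvis anatomical frame from iliac-spine markers
#'
#' @param lasis,rasis,lpsis,rpsis 3D marker positions (world frame), meters.
#' @return list with `origin` (ASIS midpoint) and `R` (3 x 3 rotation whose
#'   columns are the right, forward and up axes in world coordinates).
#' @export
pelvis_frame <- function(lasis, rasis, lpsis, rpsis) {
  pts <- rbind(lasis, rasis, lpsis, rpsis)
  if (any(!is.finite(pts))) stop("geometry error: non-finite pelvis marker")
  right <- rasis - lasis
  nr <- sqrt(sum(right^2))
  if (nr < 1e-9) stop("geometry error: ASIS markers coincide")
  right <- right / nr
  origin <- (lasis + rasis) / 2
  psis_mid <- (lpsis + rpsis) / 2
  fwd <- origin - psis_mid
  fwd <- fwd - sum(fwd * right) * right
  nf <- sqrt(sum(fwd^2))
  if (nf < 1e-9) stop("geometry error: pelvis markers are collinear")
  fwd <- fwd / nf
  up <- c(right[2] * fwd[3] - right[3] * fwd[2],
          right[3] * fwd[1] - right[1] * fwd[3],
          right[1] * fwd[2] - right[2] * fwd[1])
  list(origin = as.numeric(origin), R = cbind(right, fwd, up, deparse.level = 0))
}

#' Per-sample pelvis frames of a marker set
#'
#' @param ms a [marker_set()] containing `LASIS`, `RASIS`, `LPSIS`, `RPSIS`.
#' @return list of per-sample [pelvis_frame()] transforms.
#' @export
pelvis_frames <- function(ms) {
  need <- c("LASIS", "RASIS", "LPSIS", "RPSIS")
  miss <- setdiff(need, names(ms$trajectories))
  if (length(miss)) stop("configuration error: missing marker ", miss[1])
  tr <- lapply(need, function(n) ms$trajectories[[n]]$values)
  lapply(seq_len(ms$n), function(i)
    pelvis_frame(tr[[1]][i, ], tr[[2]][i, ], tr[[3]][i, ], tr[[4]][i, ]))
}

#' Express marker trajectories in the pelvis frame
#'
#' Removes whole-body translation and pelvis rotation so that gait-event
#' geometry ("anterior", "vertical") is defined relative to the subject.
#'
#' @param ms a [marker_set()].
#' @param frames per-sample transforms from [pelvis_frames()] (one per
#'   sample).
#' @param invert if `TRUE`, applies the inverse mapping (pelvis-frame
#'   coordinates back to the world).
#' @return a [marker_set()] in pelvis coordinates.
#' @export
express_in_pelvis <- function(ms, frames, invert = FALSE) {
  if (length(frames) != ms$n)
    stop("alignment error: one pelvis frame per sample is required")
  out <- ms
  for (lab in names(ms$trajectories)) {
    v <- ms$trajectories[[lab]]$values
    w <- v
    for (i in seq_len(ms$n)) {
      f <- frames[[i]]
      w[i, ] <- if (invert) f$R %*% v[i, ] + f$origin
                else crossprod(f$R, v[i, ] - f$origin)
    }
    out$trajectories[[lab]]$values <- w
  }
  out
}
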
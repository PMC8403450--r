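# Gait event detection and bookkeeping.
#
# Events are heel strikes (HS) and toe-offs (TO) per side. Marker-based
# detection offers four kinematic procedures plus a consensus combiner;
# phone-based detection works on the 2 Hz low-passed global vertical
# acceleration. "Horizontal" means the plane orthogonal to the pelvis
# vertical axis; "anterior" is the pelvis forward axis, so all marker
# procedures expect pelvis-expressed trajectories.

#' Construct a gait-event table
#'
#' @param time event times, seconds.
#' @param kind `"heel_strike"` or `"toe_off"` (recycled).
#' @param side `"left"` or `"right"` (recycled).
#' @param source originating system tag (`marker`, `imu`, `phone`, `truth`).
#' @param method detector tag.
#' @return data.frame of class `gait_events`, ordered by time.
#' @export
gait_events <- function(time, kind, side, source = "marker", method = "") {
  if (length(time) == 0L)
    return(structure(data.frame(time = numeric(0), kind = character(0),
                                side = character(0), source = character(0),
                                method = character(0)),
                     class = c("gait_events", "data.frame")))
  kind <- match.arg(kind, c("heel_strike", "toe_off"), several.ok = TRUE)
  side <- match.arg(side, c("left", "right"), several.ok = TRUE)
  df <- data.frame(time = time, kind = kind, side = side,
                   source = source, method = method)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, class = c("gait_events", "data.frame"))
}

# Local maxima indices; plateaus report their FIRST sample (a double-support
# plateau of the inter-heel distance starts at the heel strike). Slopes with
# |diff| <= plateau_tol count as flat, so micro-wiggles (numeric noise,
# residual marker noise) do not push the detected maximum along a plateau.
local_maxima <- function(x, min_prominence = 0, plateau_tol = 0) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  d <- diff(x)
  rising <- FALSE
  out <- integer(0)
  start <- 1L
  for (i in seq_len(n - 1L)) {
    if (d[i] > plateau_tol) { rising <- TRUE; start <- i + 1L }
    else if (d[i] < -plateau_tol) {
      if (rising) out <- c(out, start)
      rising <- FALSE
    }
  }
  if (min_prominence > 0 && length(out)) {
    # prominence against the deepest minimum on each flank
    keep <- vapply(out, function(i) {
      left <- min(x[1:i]); right <- min(x[i:n])
      x[i] - max(left, right) >= min_prominence
    }, logical(1))
    out <- out[keep]
  }
  out
}

local_minima <- function(x, ...) local_maxima(-x, ...)

# Sign changes of a signal: last index before the sign flips in the given
# direction ("down" = + to -, "up" = - to +).
sign_changes <- function(x, direction = c("down", "up")) {
  direction <- match.arg(direction)
  s <- sign(x)
  nz <- which(s != 0)
  if (length(nz) < 2L) return(integer(0))
  out <- integer(0)
  prev <- nz[1]
  for (i in nz[-1]) {
    if (s[i] != s[prev]) {
      flip_down <- s[prev] > 0
      if ((direction == "down") == flip_down) out <- c(out, i)
    }
    prev <- i
  }
  out
}

marker_col <- function(ms, lab, col) {
  tr <- ms$trajectories[[lab]]
  if (is.null(tr)) stop("configuration error: missing marker ", lab)
  tr$values[, col]
}

#' Marker-based gait event detection
#'
#' Four kinematic procedures on pelvis-expressed heel/toe trajectories:
#' \describe{
#'   \item{interheel}{HS at local maxima of the horizontal inter-heel
#'     distance, attributed to the leading (anterior) foot. HS only.}
#'   \item{foot_com_velocity}{HS at local minima and TO at local maxima of
#'     the foot-centre (mid heel-toe) vertical velocity.}
#'   \item{coordinate}{HS at maxima of the anterior heel position, TO at
#'     maxima of the posterior toe position (minima of its anterior
#'     coordinate), both relative to the pelvis.}
#'   \item{velocity}{HS where the anterior heel velocity changes sign from
#'     positive to negative, TO where the anterior toe velocity changes
#'     from negative to positive.}
#' }
#'
#' @param ms pelvis-expressed [marker_set()] with markers `heel_L/R`,
#'   `toe_L/R` (axes: 1 right, 2 forward, 3 up).
#' @param method one of the four procedure tags.
#' @param min_prominence extremum prominence floor, meters (or m/s), to
#'   suppress jitter peaks.
#' @param source source tag carried into the events.
#' @return a [gait_events()] table (empty with a warning when nothing is
#'   found).
#' @export
detect_events_marker <- function(ms,
                                 method = c("interheel", "foot_com_velocity",
                                            "coordinate", "velocity"),
                                 min_prominence = 0.02, source = "marker") {
  method <- match.arg(method)
  tm <- ms$t0 + (seq_len(ms$n) - 1L) / ms$fs
  ev_t <- numeric(0); ev_k <- character(0); ev_s <- character(0)
  emit <- function(idx, kind, side) {
    ev_t <<- c(ev_t, tm[idx])
    ev_k <<- c(ev_k, rep(kind, length(idx)))
    ev_s <<- c(ev_s, rep(side, length(idx)))
  }
  sides <- c(left = "L", right = "R")
  if (method == "interheel") {
    hl <- cbind(marker_col(ms, "heel_L", 1), marker_col(ms, "heel_L", 2))
    hr <- cbind(marker_col(ms, "heel_R", 1), marker_col(ms, "heel_R", 2))
    d <- sqrt(rowSums((hl - hr)^2))
    idx <- local_maxima(d, min_prominence, plateau_tol = 5e-4)
    lead_left <- marker_col(ms, "heel_L", 2)[idx] >
      marker_col(ms, "heel_R", 2)[idx]
    if (any(lead_left)) emit(idx[lead_left], "heel_strike", "left")
    if (any(!lead_left)) emit(idx[!lead_left], "heel_strike", "right")
  } else {
    for (side in names(sides)) {
      sfx <- sides[[side]]
      heel_y <- marker_col(ms, paste0("heel_", sfx), 2)
      toe_y <- marker_col(ms, paste0("toe_", sfx), 2)
      if (method == "foot_com_velocity") {
        fz <- (marker_col(ms, paste0("heel_", sfx), 3) +
               marker_col(ms, paste0("toe_", sfx), 3)) / 2
        vz <- c(0, diff(fz)) * ms$fs
        emit(local_minima(vz, min_prominence * ms$fs / 4), "heel_strike", side)
        emit(local_maxima(vz, min_prominence * ms$fs / 4), "toe_off", side)
      } else if (method == "coordinate") {
        emit(local_maxima(heel_y, min_prominence), "heel_strike", side)
        emit(local_maxima(-toe_y, min_prominence), "toe_off", side)
      } else {                      # velocity
        vy_h <- c(0, diff(heel_y)) * ms$fs
        vy_t <- c(0, diff(toe_y)) * ms$fs
        emit(sign_changes(vy_h, "down"), "heel_strike", side)
        emit(sign_changes(vy_t, "up"), "toe_off", side)
      }
    }
  }
  if (!length(ev_t)) {
    warning("no gait events found (", method, ")")
    return(gait_events(numeric(0), character(0), character(0)))
  }
  gait_events(ev_t, ev_k, ev_s, source = source, method = method)
}

#' Combine per-method event candidates into a consensus stream
#'
#' Candidate events of the same kind and side lying within `window` of each
#' other are clustered (single-linkage on time); each cluster supported by
#' at least two methods (or by all available methods when fewer than two
#' supplied any candidates) emits one event at the cluster median time.
#' Overlapping ambiguous clusters resolve in earliest-median order.
#'
#' @param candidates list of [gait_events()] tables, one per method.
#' @param window clustering half-width, seconds (default 0.05).
#' @param source source tag for the combined events.
#' @return a [gait_events()] table with method tag `"consensus"`.
#' @export
consensus_events <- function(candidates, window = 0.05, source = "marker") {
  if (!length(candidates)) stop("need at least one candidate list")
  if (window <= 0) stop("window must be positive")
  all_ev <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    ev <- candidates[[i]]
    if (nrow(ev)) cbind(ev, .method_id = i) else NULL
  }))
  if (is.null(all_ev) || !nrow(all_ev))
    return(gait_events(numeric(0), character(0), character(0)))
  n_methods <- length(unique(all_ev$.method_id))
  quorum <- min(2L, n_methods)
  out_t <- numeric(0); out_k <- character(0); out_s <- character(0)
  for (kind in unique(all_ev$kind)) for (side in unique(all_ev$side)) {
    sub <- all_ev[all_ev$kind == kind & all_ev$side == side, , drop = FALSE]
    if (!nrow(sub)) next
    sub <- sub[order(sub$time), , drop = FALSE]
    cl <- cumsum(c(1, diff(sub$time) > window))
    for (g in unique(cl)) {
      grp <- sub[cl == g, , drop = FALSE]
      support <- length(unique(grp$.method_id))
      if (support >= quorum) {
        out_t <- c(out_t, stats::median(grp$time))
        out_k <- c(out_k, kind); out_s <- c(out_s, side)
      }
    }
  }
  if (!length(out_t))
    return(gait_events(numeric(0), character(0), character(0)))
  ev <- gait_events(out_t, out_k, out_s, source = source, method = "consensus")
  enforce_alternation(ev)
}

# Drop events breaking the per-side HS/TO alternation (keep the earlier of
# two same-kind neighbours). Streams carrying a single kind (e.g. the
# heel-strike-only interheel method) are left untouched.
enforce_alternation <- function(ev) {
  keep <- rep(TRUE, nrow(ev))
  for (side in unique(ev$side)) {
    idx <- which(ev$side == side)
    if (length(unique(ev$kind[idx])) < 2L) next
    last_kind <- ""
    for (i in idx) {
      if (ev$kind[i] == last_kind) keep[i] <- FALSE
      else last_kind <- ev$kind[i]
    }
  }
  structure(ev[keep, , drop = FALSE], class = class(ev))
}

#' Phone gait event detection from vertical acceleration
#'
#' The (gravity-subtracted) global vertical acceleration is low-passed with
#' a zero-phase 4th-order Butterworth at 2 Hz. Positive peaks with minimum
#' prominence and separation are located and labelled high or low against
#' the running median of the neighbouring peak amplitudes; the first nadir
#' (local minimum) after each high peak is a heel strike and after each low
#' peak a toe-off, both ipsilateral to the pocket.
#'
#' @param a_vert [uniform_series()] of vertical acceleration, m/s^2,
#'   gravity already subtracted.
#' @param side pocket side, `"left"` or `"right"`.
#' @param cutoff low-pass cutoff, Hz.
#' @param min_prominence minimum peak prominence, m/s^2.
#' @param min_separation minimum peak separation, seconds.
#' @param burn_in leading seconds ignored (fusion convergence transient).
#' @return a [gait_events()] table with source `"phone"`.
#' @export
detect_events_phone <- function(a_vert, side, cutoff = 2,
                                min_prominence = 0.3, min_separation = 0.3,
                                burn_in = 2) {
  side <- match.arg(side, c("left", "right"))
  filt <- butterworth_lowpass(a_vert, order = 4L, cutoff = cutoff)
  x <- filt$values[, 1]
  tm <- series_time(filt)
  use <- tm >= tm[1] + burn_in
  x <- x[use]; tm <- tm[use]
  pk <- local_maxima(x, min_prominence)
  # enforce minimum separation, keeping the taller peak
  if (length(pk) > 1L) {
    keep <- rep(TRUE, length(pk))
    i <- 1L
    for (j in 2L:length(pk)) {
      if (tm[pk[j]] - tm[pk[i]] < min_separation) {
        if (x[pk[j]] > x[pk[i]]) { keep[i] <- FALSE; i <- j }
        else keep[j] <- FALSE
      } else i <- j
    }
    pk <- pk[keep]
  }
  if (length(pk) < 2L) {
    warning("fewer than 2 peaks in vertical acceleration; no events")
    return(gait_events(numeric(0), character(0), character(0)))
  }
  nd <- local_minima(x)
  # label peaks high/low against the running median of the neighbouring
  # peak amplitudes (the two adjacent peaks; one at the ends)
  amp <- x[pk]
  lab <- vapply(seq_along(pk), function(i) {
    nb <- amp[c(i - 1L, i + 1L)]
    nb <- nb[!is.na(nb)]
    if (amp[i] > stats::median(nb)) "high" else "low"
  }, character(1))
  ev_t <- numeric(0); ev_k <- character(0)
  for (i in seq_along(pk)) {
    nxt <- nd[nd > pk[i]]
    if (!length(nxt)) next
    ev_t <- c(ev_t, tm[nxt[1]])
    ev_k <- c(ev_k, if (lab[i] == "high") "heel_strike" else "toe_off")
  }
  if (!length(ev_t))
    return(gait_events(numeric(0), character(0), character(0)))
  dup <- duplicated(ev_t)
  ev <- gait_events(ev_t[!dup], ev_k[!dup], side, source = "phone",
                    method = "peak_nadir")
  enforce_alternation(ev)
}

#' Match test events to reference events
#'
#' Greedy nearest-time one-to-one matching within a tolerance, separately
#' per kind and side. Test events without a reference correspondence are
#' listed unmatched and excluded from downstream agreement statistics.
#'
#' @param reference,test [gait_events()] tables.
#' @param tolerance maximum |offset|, seconds (default 0.15, about half a
#'   swing phase).
#' @return list of class `event_match_table`: `pairs` (data.frame with
#'   reference/test times, kind, side, offset), `unmatched_reference`,
#'   `unmatched_test`.
#' @export
match_events <- function(reference, test, tolerance = 0.15) {
  if (tolerance <= 0) stop("tolerance must be positive")
  pairs <- NULL
  un_ref <- NULL; un_test <- NULL
  for (kind in c("heel_strike", "toe_off")) for (side in c("left", "right")) {
    r <- reference[reference$kind == kind & reference$side == side, ]
    s <- test[test$kind == kind & test$side == side, ]
    if (!nrow(r) && !nrow(s)) next
    taken_r <- rep(FALSE, nrow(r)); taken_s <- rep(FALSE, nrow(s))
    if (nrow(r) && nrow(s)) {
      cand <- expand.grid(i = seq_len(nrow(r)), j = seq_len(nrow(s)))
      cand$d <- abs(r$time[cand$i] - s$time[cand$j])
      cand <- cand[cand$d <= tolerance, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      for (row in seq_len(nrow(cand))) {
        i <- cand$i[row]; j <- cand$j[row]
        if (!taken_r[i] && !taken_s[j]) {
          taken_r[i] <- TRUE; taken_s[j] <- TRUE
          pairs <- rbind(pairs, data.frame(
            reference_time = r$time[i], test_time = s$time[j],
            kind = kind, side = side, offset = s$time[j] - r$time[i]))
        }
      }
    }
    if (any(!taken_r)) un_ref <- rbind(un_ref, r[!taken_r, ])
    if (any(!taken_s)) un_test <- rbind(un_test, s[!taken_s, ])
  }
  if (!is.null(pairs)) pairs <- pairs[order(pairs$reference_time), ]
  structure(list(pairs = pairs %||% data.frame(),
                 unmatched_reference = un_ref %||% reference[0, ],
                 unmatched_test = un_test %||% test[0, ],
                 tolerance = tolerance),
            class = "event_match_table")
}

#' @export
print.event_match_table <- function(x, ...) {
  cat(sprintf("<event_match_table> %d pairs, %d unmatched ref, %d unmatched test (tol %.3f s)\n",
              nrow(x$pairs), nrow(x$unmatched_reference),
              nrow(x$unmatched_test), x$tolerance))
  invisible(x)
}

#' Build gait cycles from an event stream
#'
#' One cycle per consecutive ipsilateral heel-strike pair containing exactly
#' one ipsilateral toe-off; pairs violating this alternation are dropped
#' with a logged reason. The contralateral toe-off following the start heel
#' strike is attached when present (for double support).
#'
#' @param events a [gait_events()] table.
#' @return list of `gait_cycle` objects: fields `side`, `start`, `end`,
#'   `toe_off`, `contra_toe_off` (or `NA`), `source`. Drop reasons are in
#'   attribute `dropped`.
#' @export
build_cycles <- function(events) {
  cycles <- list()
  dropped <- character(0)
  for (side in c("left", "right")) {
    other <- setdiff(c("left", "right"), side)
    hs <- events$time[events$kind == "heel_strike" & events$side == side]
    to <- events$time[events$kind == "toe_off" & events$side == side]
    cto <- events$time[events$kind == "toe_off" & events$side == other]
    if (length(hs) < 2L) next
    for (i in seq_len(length(hs) - 1L)) {
      t0 <- hs[i]; t1 <- hs[i + 1L]
      inside <- to[to > t0 & to < t1]
      if (length(inside) != 1L) {
        dropped <- c(dropped, sprintf(
          "%s cycle %.3f-%.3f s: %d ipsilateral toe-offs", side, t0, t1,
          length(inside)))
        next
      }
      c_inside <- cto[cto > t0 & cto < inside]
      cycles[[length(cycles) + 1L]] <- structure(
        list(side = side, start = t0, end = t1, toe_off = inside,
             contra_toe_off = if (length(c_inside)) c_inside[1] else NA_real_,
             source = events$source[1] %||% ""),
        class = "gait_cycle")
    }
  }
  cycles <- cycles[order(vapply(cycles, `[[`, numeric(1), "start"))]
  attr(cycles, "dropped") <- dropped
  cycles
}
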
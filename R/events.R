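#' Trough-detection policy
#'
#' Troughs are operationalized as prominence-filtered local minima of a
#' centered moving average ("consistent lowest local mean"): the signal is
#' first averaged over `local_mean_window` frames, local minima of the
#' averaged signal are kept if their prominence reaches
#' `prominence_fraction` of the signal's peak-to-peak range, and minima
#' closer together than `min_separation` are resolved by keeping the
#' deeper one (ties go to the earlier frame).
#'
#' @param local_mean_window Moving-average window in frames (default 5).
#' @param min_separation Minimum separation between retained troughs in
#'   seconds (default 0.4, about half a gait cycle at fast cadence, which
#'   prevents double-detection within one cycle).
#' @param prominence_fraction Required prominence as a fraction of the
#'   signal peak-to-peak range, in `(0, 1)` (default 0.2).
#' @return A `trough_policy` object.
#' @export
trough_policy <- function(local_mean_window = 5, min_separation = 0.4,
                          prominence_fraction = 0.2) {
  if (min_separation <= 0) {
    stop(gait_error("gait_parameter_error", "min_separation must be > 0"))
  }
  if (prominence_fraction <= 0 || prominence_fraction >= 1) {
    stop(gait_error("gait_parameter_error",
                    "prominence_fraction must be in (0, 1)"))
  }
  structure(list(local_mean_window = local_mean_window,
                 min_separation = min_separation,
                 prominence_fraction = prominence_fraction),
            class = "trough_policy")
}

# centered moving mean with symmetric window shrinkage at the edges
.local_mean <- function(y, window) {
  n <- length(y)
  half <- (window - 1) %/% 2
  out <- numeric(n)
  cs <- cumsum(c(0, y))
  for (i in seq_len(n)) {
    h <- min(half, i - 1L, n - i)
    out[i] <- (cs[i + h + 1] - cs[i - h]) / (2 * h + 1)
  }
  out
}

# prominence of minima: depth below the lower of the two enclosing
# "cols" (standard peak prominence computed on the negated signal)
.trough_prominence <- function(y, troughs) {
  n <- length(y)
  vapply(troughs, function(i) {
    v <- y[i]
    # walk left until a deeper trough (or end); highest point seen bounds
    lo <- i; left_max <- -Inf
    j <- i - 1L
    while (j >= 1L) {
      if (y[j] < v) break
      if (y[j] > left_max) left_max <- y[j]
      j <- j - 1L
    }
    if (j < 1L && is.infinite(left_max)) left_max <- v
    right_max <- -Inf
    j <- i + 1L
    while (j <= n) {
      if (y[j] < v) break
      if (y[j] > right_max) right_max <- y[j]
      j <- j + 1L
    }
    if (j > n && is.infinite(right_max)) right_max <- v
    min(left_max, right_max) - v
  }, numeric(1))
}

#' Detect troughs in a cyclic gait signal
#'
#' @param signal Per-frame scalar signal (e.g. the vertical coordinate of
#'   a foot keypoint).
#' @param t Frame timestamps in seconds (same length as `signal`). If
#'   omitted, frames are assumed 1/60 s apart.
#' @param policy A [trough_policy()].
#' @return Integer vector of trough frame indices (sorted). A constant
#'   signal yields an empty result.
#' @export
#' @examples
#' t <- seq(0, 3, by = 1 / 60)
#' detect_troughs(sin(2 * pi * t), t)  # near t = 0.75, 1.75, 2.75
detect_troughs <- function(signal, t = NULL, policy = trough_policy()) {
  n <- length(signal)
  if (is.null(t)) t <- (seq_len(n) - 1) / 60
  if (n < policy$local_mean_window) {
    stop(gait_error("gait_length_error",
                    "signal shorter than local_mean_window"))
  }
  lm <- .local_mean(signal, policy$local_mean_window)
  p2p <- diff(range(lm, na.rm = TRUE))
  # constant up to numerical fuzz: no oscillation, no troughs
  if (!is.finite(p2p) ||
      p2p <= 1e-12 * max(1, max(abs(lm), na.rm = TRUE))) {
    return(integer(0))
  }

  # local minima; plateaus contribute their first frame
  d <- diff(lm)
  cand <- integer(0)
  falling <- FALSE
  last_fall_end <- NA_integer_
  for (i in seq_along(d)) {
    if (d[i] < 0) {
      falling <- TRUE
      last_fall_end <- i + 1L
    } else if (d[i] > 0) {
      if (falling) cand <- c(cand, last_fall_end)
      falling <- FALSE
    }
  }
  if (length(cand) == 0) return(integer(0))

  prom <- .trough_prominence(lm, cand)
  keep <- prom >= policy$prominence_fraction * p2p
  cand <- cand[keep]
  if (length(cand) == 0) return(integer(0))

  # enforce min_separation greedily, deepest first (ties: earlier frame)
  ord <- order(lm[cand], cand)
  accepted <- integer(0)
  for (i in cand[ord]) {
    if (all(abs(t[i] - t[accepted]) >= policy$min_separation)) {
      accepted <- c(accepted, i)
    }
  }
  sort(accepted)
}

.peaks <- function(signal, t, policy) {
  detect_troughs(-signal, t, policy)
}

# first sustained upward threshold crossing with sub-frame refinement;
# returns the refined time or NA
.onset_crossing <- function(y, t, baseline, threshold, from = 1L, to = length(y),
                            sustain = 3L) {
  thr <- baseline + threshold
  idx <- from:to
  above <- y[idx] > thr
  if (!any(above)) return(NA_real_)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(runs$values & runs$lengths >= sustain)
  if (length(k) == 0) return(NA_real_)
  i <- idx[starts[k[1]]]
  if (i <= from) return(t[i])
  # linear interpolation to the threshold, then subtract the lead the
  # threshold itself introduces using the local slope
  t_cross <- t[i - 1] + (thr - y[i - 1]) / (y[i] - y[i - 1]) * (t[i] - t[i - 1])
  j2 <- min(to, i + sustain)
  slope <- (y[j2] - y[i - 1]) / (t[j2] - t[i - 1])
  if (is.finite(slope) && slope > 0) {
    t_on <- t_cross - threshold / slope
    max(t_on, t[from])
  } else {
    t_cross
  }
}

# hysteresis zero crossings (negative to positive); returns frame indices
.zero_crossings_up <- function(d, delta) {
  n <- length(d)
  out <- integer(0)
  armed <- FALSE
  for (i in seq_len(n)) {
    if (!is.finite(d[i])) next
    if (d[i] < -delta) armed <- TRUE
    if (armed && d[i] > delta) {
      # crossing frame: nearest to zero within the transition
      lo <- i
      while (lo > 1 && is.finite(d[lo - 1]) && d[lo - 1] <= delta &&
             d[lo - 1] >= -delta) lo <- lo - 1
      seg <- lo:i
      out <- c(out, seg[which.min(abs(d[seg]))])
      armed <- FALSE
    }
  }
  out
}

# Minimum physically meaningful signal excursions (meters). Signals whose
# peak-to-peak range stays below these floors are treated as "no gait"
# (e.g. a subject standing still) rather than searched for events.
.EVENT_FLOORS <- c(vertical = 0.01, progression = 0.05)

# frames during which the subject is walking: robust pelvis progression
# velocity (0.25 s regression baseline on a locally averaged signal)
# above 0.05 m/s, dilated by a quarter second so events at gait onset
# and termination are kept. Keypoint wobble while standing cannot fire
# the gate because the averaging suppresses frame-to-frame noise.
.gait_gate <- function(prog_ref, t, threshold = 0.05, margin_s = 0.25) {
  n <- length(t)
  if (n < 3) return(rep(TRUE, n))
  dt <- stats::median(diff(t))
  p <- .local_mean(.fill_na(prog_ref), max(3L, 2L * round(0.125 / dt) + 1L))
  k <- max(1L, round(0.125 / dt))
  lo <- pmax(1L, seq_len(n) - k)
  hi <- pmin(n, seq_len(n) + k)
  vel <- (p[hi] - p[lo]) / ((hi - lo) * dt)
  moving <- abs(vel) > threshold
  # walking must be sustained: brief threshold crossings (boundary-frame
  # noise, postural sway) are discarded before the margin is applied
  min_run <- max(2L, round(0.3 / dt))
  runs <- rle(moving)
  runs$values[runs$values & runs$lengths < min_run] <- FALSE
  moving <- inverse.rle(runs)
  m <- round(margin_s / dt)
  idx <- which(moving)
  if (length(idx) == 0) return(moving)
  gate <- rep(FALSE, n)
  for (i in idx) gate[max(1, i - m):min(n, i + m)] <- TRUE
  gate
}

#' Detect gait events
#'
#' Detects the five-event vocabulary per side on a smoothed world track:
#' \describe{
#'   \item{TOE_OFF}{Troughs of the big-toe vertical coordinate (the
#'     ankle is used as fallback when toe quality is predominantly low).}
#'   \item{HEEL_STRIKE}{Local maxima of heel progression relative to the
#'     pelvis (forward-position extremum rule, the standard kinematic
#'     approach for marker data).}
#'   \item{HEEL_RISE}{Onset of heel vertical displacement above its
#'     early-stance baseline within each stance interval, with sub-frame
#'     slope-corrected threshold crossing.}
#'   \item{FEET_ADJACENT}{Minima of the inter-ankle progression distance;
#'     the event is attributed to the swinging side.}
#'   \item{TIBIA_VERTICAL}{Frames where the knee passes directly above the
#'     ankle along the progression axis (signed knee-ankle progression
#'     difference crosses zero with hysteresis).}
#' }
#' Signals whose excursion stays below small physical floors (1 cm
#' vertical, 5 cm progression) produce no events, so a standing subject
#' yields an empty event list. Events are further gated to the interval
#' in which the pelvis is actually progressing (speed above 0.05 m/s,
#' with a 0.25 s margin), which suppresses spurious extrema from
#' keypoint wobble while the subject stands before and after the walk.
#'
#' @param track A smoothed `world_track` (see [smooth_series()]).
#' @param walkway A [walkway_definition()].
#' @param policy A [trough_policy()] governing extremum detection.
#' @return A `gait_events` data frame: columns `type`, `side`, `frame`,
#'   `t`, ordered by time; strictly increasing within each (type, side).
#' @export
detect_events <- function(track, walkway, policy = trough_policy()) {
  stopifnot(inherits(track, "world_track"),
            inherits(walkway, "walkway_definition"))
  t <- frame_times(track)
  q <- kp_mat(track, "quality")
  needed <- c("l_heel", "r_heel", "l_big_toe", "r_big_toe",
              "l_ankle", "r_ankle", "l_knee", "r_knee", "mid_hip")
  usable <- colMeans(q[, needed, drop = FALSE] > 0)
  if (any(usable == 0)) {
    stop(gait_error("gait_insufficient_data",
                    sprintf("joint(s) missing throughout: %s",
                            paste(needed[usable == 0], collapse = ", "))))
  }
  prog <- apply(.progression_matrix(track, walkway), 2, .fill_na)
  height <- apply(.height_matrix(track, walkway), 2, .fill_na)
  dt <- if (length(t) > 1) stats::median(diff(t)) else 1 / 60
  gate <- .gait_gate(prog[, "mid_hip"], t)

  ev <- list()
  add <- function(type, side, frames) {
    frames <- frames[is.finite(frames)]
    frames <- frames[gate[as.integer(frames)]]
    if (length(frames) == 0) return()
    ev[[length(ev) + 1]] <<- data.frame(
      type = type, side = side, frame = as.integer(frames),
      t = t[as.integer(frames)], stringsAsFactors = FALSE)
  }

  for (side in c("LEFT", "RIGHT")) {
    toe <- .side_joint("big_toe", side)
    ankle <- .side_joint("ankle", side)
    heel <- .side_joint("heel", side)
    knee <- .side_joint("knee", side)

    # TOE_OFF: troughs of the foot vertical signal
    foot_joint <- if (mean(q[, toe] > 0) >= 0.5) toe else ankle
    hsig <- height[, foot_joint]
    if (.excursion(hsig) >= .EVENT_FLOORS["vertical"]) {
      add("TOE_OFF", side, detect_troughs(hsig, t, policy))
    }

    # HEEL_STRIKE: forward-position extrema of heel relative to pelvis
    rel <- prog[, heel] - prog[, "mid_hip"]
    hs <- integer(0)
    if (.excursion(rel) >= .EVENT_FLOORS["progression"]) {
      hs <- .peaks(rel, t, policy)
      add("HEEL_STRIKE", side, hs)
    }

    # TIBIA_VERTICAL: knee passes over ankle
    dk <- prog[, knee] - prog[, ankle]
    if (.excursion(dk) >= .EVENT_FLOORS["progression"]) {
      delta <- 0.1 * .excursion(dk)
      add("TIBIA_VERTICAL", side, .zero_crossings_up(dk, delta))
    }

    # HEEL_RISE: onset of heel lift inside each stance interval
    hh <- height[, heel]
    if (.excursion(hh) >= 2 * .EVENT_FLOORS["vertical"] && length(hs) > 0) {
      to_frames <- ev_frames(ev, "TOE_OFF", side)
      thr <- 0.1 * .excursion(hh)
      for (f_hs in hs) {
        f_to <- to_frames[to_frames > f_hs]
        if (length(f_to) == 0) next
        f_to <- f_to[1]
        if (f_to - f_hs < 4) next
        base <- min(hh[f_hs:f_to], na.rm = TRUE)
        t_on <- .onset_crossing(hh, t, base, thr,
                                from = f_hs, to = f_to)
        if (is.finite(t_on)) {
          add("HEEL_RISE", side, which.min(abs(t - t_on)))
        }
      }
    }
  }

  # FEET_ADJACENT: minima of inter-ankle progression distance
  gap <- abs(prog[, "l_ankle"] - prog[, "r_ankle"])
  if (.excursion(gap) >= .EVENT_FLOORS["progression"]) {
    fa <- detect_troughs(gap, t, policy)
    if (length(fa) > 0) {
      vl <- abs(.central_diff(prog[, "l_ankle"], dt))
      vr <- abs(.central_diff(prog[, "r_ankle"], dt))
      for (f in fa) {
        side <- if (vl[f] >= vr[f]) "LEFT" else "RIGHT"
        add("FEET_ADJACENT", side, f)
      }
    }
  }

  if (length(ev) == 0) {
    out <- data.frame(type = character(0), side = character(0),
                      frame = integer(0), t = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    out <- do.call(rbind, ev)
    out <- out[order(out$t, out$type, out$side), , drop = FALSE]
    # enforce strict ordering per (type, side): drop exact duplicates
    key <- paste(out$type, out$side, out$frame)
    out <- out[!duplicated(key), , drop = FALSE]
    rownames(out) <- NULL
  }
  class(out) <- c("gait_events", "data.frame")
  out
}

# replace residual NAs (e.g. unfilled detector dropouts at the recording
# boundaries) by linear interpolation / nearest-value extension so the
# extremum scans stay total; detection signals only, never the track
.fill_na <- function(y) {
  ok <- is.finite(y)
  if (all(ok) || !any(ok)) return(y)
  stats::approx(which(ok), y[ok], xout = seq_along(y), rule = 2)$y
}

.excursion <- function(x) {
  r <- range(x, na.rm = TRUE)
  if (!all(is.finite(r))) return(0)
  r[2] - r[1]
}

.central_diff <- function(y, dt) {
  n <- length(y)
  if (n < 2) return(rep(0, n))
  c(y[2] - y[1], (y[3:n] - y[1:(n - 2)]) / 2, y[n] - y[n - 1]) / dt
}

ev_frames <- function(ev_list, type, side) {
  if (length(ev_list) == 0) return(integer(0))
  df <- do.call(rbind, ev_list)
  sort(df$frame[df$type == type & df$side == side])
}

#' Segment stance and swing phases
#'
#' Pairs alternating ipsilateral heel strikes and toe offs into phases:
#' stance runs from a heel strike to the next toe off of the same side,
#' swing from a toe off to the next heel strike. Incomplete boundary
#' phases are dropped; two consecutive same-type events trigger a
#' sequencing warning and the intervening phase is skipped.
#'
#' @param events A `gait_events` data frame from [detect_events()].
#' @return A `gait_phases` data frame: columns `side`, `phase`
#'   (`"STANCE"`/`"SWING"`), `start_t`, `end_t`; per side the phases
#'   alternate and tile the detected interval without overlap.
#' @export
segment_phases <- function(events) {
  out <- list()
  for (side in c("LEFT", "RIGHT")) {
    e <- events[events$side == side &
                  events$type %in% c("HEEL_STRIKE", "TOE_OFF"), ,
                drop = FALSE]
    e <- e[order(e$t), , drop = FALSE]
    if (nrow(e) < 2) next
    i <- 1L
    while (i < nrow(e)) {
      a <- e[i, ]; b <- e[i + 1L, ]
      if (a$type == b$type) {
        warning(gait_warning("gait_sequencing_warning",
                             sprintf("consecutive %s events on %s side at %.3fs",
                                     a$type, side, b$t)))
        i <- i + 1L
        next
      }
      phase <- if (a$type == "HEEL_STRIKE") "STANCE" else "SWING"
      out[[length(out) + 1]] <- data.frame(
        side = side, phase = phase, start_t = a$t, end_t = b$t,
        stringsAsFactors = FALSE)
      i <- i + 1L
    }
  }
  if (length(out) == 0) {
    res <- data.frame(side = character(0), phase = character(0),
                      start_t = numeric(0), end_t = numeric(0),
                      stringsAsFactors = FALSE)
  } else {
    res <- do.call(rbind, out)
    res <- res[order(res$side, res$start_t), , drop = FALSE]
    rownames(res) <- NULL
  }
  class(res) <- c("gait_phases", "data.frame")
  res
}
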
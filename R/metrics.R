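#' Walkway crossing times
#'
#' Times at which the reference joint crosses the start (progression 0)
#' and end (progression = walkway length) lines, by linear interpolation
#' between the bracketing frames.
#'
#' @param progression Per-frame progression in meters, as returned by
#'   [project_to_walkway_axis()] (frame times in attribute `"t"`, or pass
#'   `t`).
#' @param walkway A [walkway_definition()].
#' @param t Frame timestamps; defaults to `attr(progression, "t")`.
#' @return Named numeric vector `c(t_start, t_end)` in seconds.
#' @export
crossing_times <- function(progression, walkway, t = NULL) {
  if (is.null(t)) t <- attr(progression, "t")
  stopifnot(length(t) == length(progression))
  up_cross <- function(level) {
    i <- which(progression >= level)
    if (length(i) == 0) {
      stop(gait_error("gait_incomplete_walk",
                      sprintf("walkway line at %.2f m never crossed", level)))
    }
    i <- i[1]
    if (i == 1L) {
      if (abs(progression[1] - level) < 1e-9) return(t[1])
      stop(gait_error("gait_incomplete_walk",
                      sprintf("recording starts beyond the %.2f m line",
                              level)))
    }
    p0 <- progression[i - 1]; p1 <- progression[i]
    if (p1 == p0) return(t[i])
    t[i - 1] + (level - p0) / (p1 - p0) * (t[i] - t[i - 1])
  }
  c(t_start = up_cross(0), t_end = up_cross(walkway$length))
}

# movement onset: first time the reference joint's progression velocity
# exceeds `threshold` m/s for at least `sustain_s` seconds
.movement_onset <- function(progression, t, threshold = 0.05,
                            sustain_s = 0.2) {
  n <- length(t)
  if (n < 3) return(NA_real_)
  dt <- stats::median(diff(t))
  vel <- .central_diff(progression, dt)
  sustain <- max(2L, ceiling(sustain_s / dt))
  above <- vel > threshold
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  k <- which(runs$values & runs$lengths >= sustain)
  if (length(k) == 0) return(NA_real_)
  t[starts[k[1]]]
}

# heel placement: mean heel progression over the interior of the stance
# interval; averaging over the plateau suppresses per-frame pixel noise
.heel_placement <- function(prog_heel, t, t_hs, t_to = NA_real_) {
  if (is.na(t_to) || t_to <= t_hs) t_to <- t_hs + 0.25
  span <- t_to - t_hs
  lo <- t_hs + 0.15 * span
  hi <- t_to - 0.15 * span
  sel <- t >= lo & t <= hi
  if (!any(sel)) sel <- which.min(abs(t - t_hs))
  mean(prog_heel[sel], na.rm = TRUE)
}

#' Compute spatiotemporal gait metrics
#'
#' Derives the standard walkway-referenced gait parameters from a
#' (smoothed) world track, detected events and phases:
#' \itemize{
#'   \item gait speed = walkway length / walk time (start to end line
#'     crossing of the pelvis);
#'   \item stride length = progression distance between consecutive
#'     ipsilateral heel strikes, per side (heel placements are estimated
#'     as the mean heel progression over the stance plateau);
#'   \item step length = progression distance between consecutive
#'     contralateral heel strikes;
#'   \item step count = heel strikes inside the walkway interval; cadence
#'     = step count / walk time x 60;
#'   \item base of support during double support;
#'   \item reaction time = movement onset minus command time (when the
#'     command time is given); ignition time = start-line crossing minus
#'     movement onset. Movement onset is the first time pelvis progression
#'     velocity exceeds 0.05 m/s sustained for 0.2 s.
#' }
#' Preconditions that fail (e.g. the walk never reaches the end line, or
#' fewer than two ipsilateral heel strikes) yield partial metrics with
#' explicit `NA` fields and a note, never silent zeros.
#'
#' @param world A smoothed `world_track`.
#' @param events A `gait_events` data frame.
#' @param phases A `gait_phases` data frame.
#' @param walkway A [walkway_definition()].
#' @param command_t Optional command time (seconds) for reaction time.
#' @param reference_joint Joint for progression (default `"mid_hip"`).
#' @return A `gait_metrics` list with fields `gait_speed`, `walk_time`,
#'   `t_start`, `t_end`, `stride_length_mean`, `stride_length_sd`,
#'   `stride_length_left`, `stride_length_right`, `step_length_mean`,
#'   `step_length_sd`, `step_count`, `cadence`, `base_of_support`,
#'   `movement_onset`, `reaction_time`, `ignition_time`, `notes`.
#' @export
compute_metrics <- function(world, events, phases, walkway,
                            command_t = NULL,
                            reference_joint = "mid_hip") {
  t <- frame_times(world)
  prog <- .progression_matrix(world, walkway)
  prog_ref <- prog[, reference_joint]
  notes <- character(0)

  crossings <- tryCatch(crossing_times(prog_ref, walkway, t),
                        gait_incomplete_walk = function(e) {
                          notes <<- c(notes, conditionMessage(e))
                          NULL
                        })
  if (is.null(crossings)) {
    t_start <- NA_real_; t_end <- NA_real_
    walk_time <- NA_real_; speed <- NA_real_
  } else {
    t_start <- crossings[["t_start"]]; t_end <- crossings[["t_end"]]
    walk_time <- t_end - t_start
    speed <- walkway$length / walk_time
  }

  onset <- .movement_onset(prog_ref, t)
  reaction <- if (!is.null(command_t) && is.finite(onset)) {
    onset - command_t
  } else NA_real_
  ignition <- if (is.finite(onset) && is.finite(t_start)) {
    t_start - onset
  } else NA_real_

  # heel placements per heel strike
  hs <- events[events$type == "HEEL_STRIKE", , drop = FALSE]
  hs <- hs[order(hs$t), , drop = FALSE]
  to_times <- function(side) {
    sort(events$t[events$type == "TOE_OFF" & events$side == side])
  }
  placement <- rep(NA_real_, nrow(hs))
  for (i in seq_len(nrow(hs))) {
    side <- hs$side[i]
    heel <- .side_joint("heel", side)
    tos <- to_times(side)
    t_to <- tos[tos > hs$t[i]]
    t_to <- if (length(t_to) > 0) t_to[1] else NA_real_
    placement[i] <- .heel_placement(prog[, heel], t, hs$t[i], t_to)
  }
  hs$placement <- placement

  in_walk <- if (is.finite(t_start) && is.finite(t_end)) {
    hs$t >= t_start & hs$t <= t_end
  } else rep(FALSE, nrow(hs))
  hw <- hs[in_walk, , drop = FALSE]

  stride_by_side <- c(LEFT = NA_real_, RIGHT = NA_real_)
  strides <- numeric(0)
  for (side in c("LEFT", "RIGHT")) {
    p <- hw$placement[hw$side == side]
    if (length(p) >= 2) {
      d <- diff(p)
      stride_by_side[side] <- mean(d)
      strides <- c(strides, d)
    }
  }
  if (length(strides) == 0) {
    notes <- c(notes,
               "fewer than 2 ipsilateral heel strikes inside the walkway; stride statistics unavailable")
  }
  steps <- numeric(0)
  if (nrow(hw) >= 2) {
    for (i in 2:nrow(hw)) {
      if (hw$side[i] != hw$side[i - 1]) {
        steps <- c(steps, hw$placement[i] - hw$placement[i - 1])
      }
    }
  }

  step_count <- if (is.finite(t_start) && is.finite(t_end)) {
    nrow(hw)
  } else NA_integer_
  cadence <- if (!is.na(step_count) && is.finite(walk_time) &&
                 walk_time > 0) {
    step_count / walk_time * 60
  } else NA_real_

  bos <- withCallingHandlers(
    base_of_support(world, phases, walkway),
    gait_undefined_metric = function(w) {
      notes <<- c(notes, conditionMessage(w))
      invokeRestart("muffleWarning")
    })

  out <- list(
    gait_speed = speed,
    walk_time = walk_time,
    t_start = t_start,
    t_end = t_end,
    stride_length_mean = if (length(strides) > 0) mean(strides) else NA_real_,
    stride_length_sd = if (length(strides) > 1) stats::sd(strides) else NA_real_,
    stride_length_left = stride_by_side[["LEFT"]],
    stride_length_right = stride_by_side[["RIGHT"]],
    step_length_mean = if (length(steps) > 0) mean(steps) else NA_real_,
    step_length_sd = if (length(steps) > 1) stats::sd(steps) else NA_real_,
    step_count = step_count,
    cadence = cadence,
    base_of_support = bos,
    movement_onset = onset,
    reaction_time = reaction,
    ignition_time = ignition,
    notes = notes
  )
  class(out) <- "gait_metrics"
  out
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat("<gait_metrics>\n")
  fmt <- function(v, unit) {
    if (is.null(v) || length(v) == 0 || !is.finite(v)) "NA"
    else sprintf("%.3f %s", v, unit)
  }
  cat("  gait speed:     ", fmt(x$gait_speed, "m/s"), "\n")
  cat("  walk time:      ", fmt(x$walk_time, "s"), "\n")
  cat("  stride length:  ", fmt(x$stride_length_mean, "m"),
      if (is.finite(x$stride_length_sd %||% NA))
        sprintf("(sd %.3f)", x$stride_length_sd) else "", "\n")
  cat("  step length:    ", fmt(x$step_length_mean, "m"), "\n")
  cat("  step count:     ",
      if (is.na(x$step_count)) "NA" else x$step_count, "\n")
  cat("  cadence:        ", fmt(x$cadence, "steps/min"), "\n")
  cat("  base of support:", fmt(x$base_of_support, "m"), "\n")
  cat("  reaction time:  ", fmt(x$reaction_time, "s"), "\n")
  cat("  ignition time:  ", fmt(x$ignition_time, "s"), "\n")
  if (length(x$notes) > 0) {
    cat("  notes:\n")
    for (nte in x$notes) cat("   -", nte, "\n")
  }
  invisible(x)
}
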
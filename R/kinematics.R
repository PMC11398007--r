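# vectorized included angle (degrees) at vertex b
.angle_deg <- function(ax, ay, bx, by, cx, cy) {
  v1x <- ax - bx; v1y <- ay - by
  v2x <- cx - bx; v2y <- cy - by
  n1 <- sqrt(v1x^2 + v1y^2)
  n2 <- sqrt(v2x^2 + v2y^2)
  cosv <- (v1x * v2x + v1y * v2y) / (n1 * n2)
  out <- acos(pmin(1, pmax(-1, cosv))) * 180 / pi
  out[n1 < 1e-9 | n2 < 1e-9] <- NA_real_
  out
}

#' Included angle at a joint vertex
#'
#' The angle between the vectors from vertex `b` to `a` and from `b` to
#' `c`, in degrees, computed as
#' `acos(((a-b) . (c-b)) / (|a-b| |c-b|))` with the cosine argument clamped
#' to `[-1, 1]` so the result is always in `[0, 180]`. The angle is
#' invariant under rotation, translation and uniform scaling of the point
#' triple, and symmetric in `a` and `c`.
#'
#' @param a,b,c Length-2 numeric points (2D); `b` is the vertex.
#' @return Angle in degrees in `[0, 180]`.
#' @export
#' @examples
#' joint_angle(c(1, 0), c(0, 0), c(0, 1))  # 90
joint_angle <- function(a, b, c) {
  stopifnot(length(a) == 2L, length(b) == 2L, length(c) == 2L)
  th <- .angle_deg(a[1], a[2], b[1], b[2], c[1], c[2])
  if (is.na(th)) {
    stop(gait_error("gait_degenerate_geometry",
                    "degenerate vertex: a or c coincides with b"))
  }
  th
}

#' Default joint-angle definitions
#'
#' Each definition is a triple `(a, b, c)` with `b` the vertex: knee =
#' (hip, knee, ankle), hip = (shoulder, hip, knee), ankle = (knee, ankle,
#' big toe), per side. Override by passing your own list of such triples
#' to [angle_traces()].
#'
#' @return Named list of definitions, each a list with elements `name`,
#'   `a`, `b`, `c` (joint names).
#' @export
angle_definitions <- function() {
  defs <- list()
  for (side in c("LEFT", "RIGHT")) {
    p <- if (side == "LEFT") "l" else "r"
    defs[[paste0(p, "_knee_angle")]] <- list(
      name = paste0(p, "_knee_angle"),
      a = .side_joint("hip", side), b = .side_joint("knee", side),
      c = .side_joint("ankle", side))
    defs[[paste0(p, "_hip_angle")]] <- list(
      name = paste0(p, "_hip_angle"),
      a = .side_joint("shoulder", side), b = .side_joint("hip", side),
      c = .side_joint("knee", side))
    defs[[paste0(p, "_ankle_angle")]] <- list(
      name = paste0(p, "_ankle_angle"),
      a = .side_joint("knee", side), b = .side_joint("ankle", side),
      c = .side_joint("big_toe", side))
  }
  defs
}

# pull planar coordinate matrices out of any track type
.planar_coords <- function(track) {
  if (inherits(track, "world_track")) {
    list(x = kp_mat(track, "X"), y = kp_mat(track, "Y"))
  } else if (inherits(track, "camera_track")) {
    list(x = kp_mat(track, "xp"), y = kp_mat(track, "yp"))
  } else if (inherits(track, "keypoint_series")) {
    list(x = kp_mat(track, "x"), y = kp_mat(track, "y"))
  } else {
    stop(gait_error("gait_configuration_error",
                    "track must be a keypoint series, camera or world track"))
  }
}

#' Per-frame joint-angle traces
#'
#' Evaluates each angle definition on every frame of a (typically
#' smoothed) track. By default angles are computed on 2D coordinates as
#' seen by the camera (the angle formula is planar); frames where any of
#' the three joints is missing (quality 0 or non-finite) are masked
#' invalid.
#'
#' @param track A smoothed `camera_track`, `world_track` or
#'   [keypoint_series()].
#' @param definitions List of angle definitions as produced by
#'   [angle_definitions()].
#' @return A `joint_angle_traces` data frame: columns `name`, `frame`,
#'   `t`, `theta` (degrees), `valid`.
#' @export
angle_traces <- function(track, definitions = angle_definitions()) {
  co <- .planar_coords(track)
  q <- kp_mat(track, "quality")
  t <- frame_times(track)
  nf <- length(t)
  res <- vector("list", length(definitions))
  for (k in seq_along(definitions)) {
    d <- definitions[[k]]
    for (nm in c("a", "b", "c")) {
      if (!(d[[nm]] %in% .joint_table$name)) {
        stop(gait_error("gait_configuration_error",
                        sprintf("unknown joint '%s' in angle definition '%s'",
                                d[[nm]], d$name)))
      }
    }
    th <- .angle_deg(co$x[, d$a], co$y[, d$a],
                     co$x[, d$b], co$y[, d$b],
                     co$x[, d$c], co$y[, d$c])
    valid <- q[, d$a] > 0 & q[, d$b] > 0 & q[, d$c] > 0 & is.finite(th)
    th[!valid] <- NA_real_
    res[[k]] <- data.frame(name = d$name, frame = seq_len(nf), t = t,
                           theta = th, valid = valid,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("joint_angle_traces", "data.frame")
  out
}

#' Base of support
#'
#' Mean mediolateral distance between the left and right ankles during
#' double support (both feet in stance), measured along the in-ground-plane
#' axis orthogonal to walkway progression. A stability measure; undefined
#' when the recording contains no double-support frames.
#'
#' @param world A `world_track`.
#' @param phases Stance/swing phases from [segment_phases()].
#' @param walkway A [walkway_definition()].
#' @return Base of support in meters, or `NA` (with a warning) when no
#'   double-support frames exist.
#' @export
base_of_support <- function(world, phases, walkway) {
  stopifnot(inherits(world, "world_track"))
  t <- frame_times(world)
  in_stance <- function(side) {
    ph <- phases[phases$side == side & phases$phase == "STANCE", , drop = FALSE]
    res <- rep(FALSE, length(t))
    for (i in seq_len(nrow(ph))) {
      res <- res | (t >= ph$start_t[i] & t <= ph$end_t[i])
    }
    res
  }
  ds <- in_stance("LEFT") & in_stance("RIGHT")
  if (!any(ds)) {
    warning(gait_warning("gait_undefined_metric",
                         "no double-support frames; base of support undefined"))
    return(NA_real_)
  }
  lat <- .lateral_matrix(world, walkway)
  mean(abs(lat[ds, "l_ankle"] - lat[ds, "r_ankle"]), na.rm = TRUE)
}
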
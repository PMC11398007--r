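#' Camera intrinsics
#'
#' Pinhole intrinsics used to normalize pixel coordinates: focal lengths
#' `fx`, `fy` and principal point `cx`, `cy`, all in pixels.
#'
#' @param fx,fy Focal lengths (pixels); must be positive.
#' @param cx,cy Principal point offsets (pixels).
#' @return A `camera_intrinsics` object.
#' @export
#' @examples
#' cam <- camera_intrinsics(800, 800, 640, 360)
camera_intrinsics <- function(fx, fy, cx, cy) {
  if (!is.finite(fx) || !is.finite(fy) || fx <= 0 || fy <= 0) {
    stop(gait_error("gait_parameter_error",
                    "focal lengths fx and fy must be positive"))
  }
  structure(list(fx = fx, fy = fy, cx = cx, cy = cy),
            class = "camera_intrinsics")
}

#' Per-frame subject depth
#'
#' Depth samples (meters from the camera) for every frame, either one
#' shared scalar per frame (broadcast to all joints) or a full
#' frames-by-25 matrix, plus the reference depth `z0` that anchors the
#' world view: world coordinates are expressed in multiples of `z0`.
#'
#' @param t Frame timestamps (seconds).
#' @param z Depths: numeric vector (per frame) or frames x 25 matrix
#'   (per joint). All values must be positive.
#' @param z0 Reference depth in meters; positive.
#' @return A `depth_track` object with `z` stored as a frames x 25 matrix.
#' @export
depth_track <- function(t, z, z0) {
  if (!is.finite(z0) || z0 <= 0) {
    stop(gait_error("gait_parameter_error", "z0 must be positive"))
  }
  if (is.matrix(z)) {
    stopifnot(nrow(z) == length(t), ncol(z) == 25L)
  } else {
    stopifnot(length(z) == length(t))
    z <- matrix(rep(as.numeric(z), 25L), ncol = 25L)
  }
  if (any(!is.finite(z)) || any(z <= 0)) {
    stop(gait_error("gait_parameter_error", "all depths must be positive"))
  }
  colnames(z) <- .joint_table$name
  structure(list(t = as.numeric(t), z = z, z0 = z0), class = "depth_track")
}

# shared track builder
.track_df <- function(t, a, b, quality, names2, cls, extra_attrs = list()) {
  n <- length(t)
  out <- data.frame(
    frame = rep(seq_len(n), each = 25L),
    t = rep(t, each = 25L),
    joint = rep(.joint_table$name, times = n),
    stringsAsFactors = FALSE
  )
  out[[names2[1]]] <- as.vector(t(a))
  out[[names2[2]]] <- as.vector(t(b))
  out$quality <- as.vector(t(quality))
  for (nm in names(extra_attrs)) attr(out, nm) <- extra_attrs[[nm]]
  class(out) <- c(cls, "data.frame")
  out
}

#' Screen to camera view
#'
#' Normalizes pixel coordinates by the camera intrinsics:
#' `x' = (x - cx) / fx`, `y' = (y - cy) / fy`. The transform is affine and
#' invertible; quality and timestamps are carried through unchanged.
#'
#' @param series A [keypoint_series()] (screen view, pixels).
#' @param cam A [camera_intrinsics()].
#' @return A `camera_track`: long data frame with columns `frame`, `t`,
#'   `joint`, `xp`, `yp`, `quality`.
#' @export
#' @examples
#' cam <- camera_intrinsics(800, 800, 640, 360)
#' walk <- simulate_walk(walk_spec(seed = 1))
#' ct <- to_camera_view(walk$series, cam)
to_camera_view <- function(series, cam) {
  stopifnot(inherits(series, "keypoint_series"),
            inherits(cam, "camera_intrinsics"))
  t <- frame_times(series)
  xp <- (kp_mat(series, "x") - cam$cx) / cam$fx
  yp <- (kp_mat(series, "y") - cam$cy) / cam$fy
  .track_df(t, xp, yp, kp_mat(series, "quality"),
            c("xp", "yp"), "camera_track",
            list(camera = cam,
                 nominal_fps = attr(series, "nominal_fps")))
}

#' Camera view back to pixels
#'
#' Inverse of [to_camera_view()]; recovers the screen-view series exactly
#' (to numerical precision).
#'
#' @param track A `camera_track`.
#' @param cam The same [camera_intrinsics()] used for normalization.
#' @return A [keypoint_series()].
#' @export
camera_to_pixels <- function(track, cam) {
  stopifnot(inherits(track, "camera_track"))
  t <- frame_times(track)
  x <- kp_mat(track, "xp") * cam$fx + cam$cx
  y <- kp_mat(track, "yp") * cam$fy + cam$cy
  series_from_mats(t, x, y, kp_mat(track, "quality"),
                   nominal_fps = attr(track, "nominal_fps") %||% 60)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Camera view to depth-scaled world view
#'
#' Lifts normalized camera coordinates to a 3D world view using per-frame
#' depth. Two conventions are provided:
#' \describe{
#'   \item{pinhole (default)}{`X = x' * (z / z0)`, `Y = y' * (z / z0)`,
#'     `Z = z / z0`: standard back-projection expressed in multiples of the
#'     reference depth `z0`, so lateral displacements keep their metric
#'     meaning at every depth.}
#'   \item{as_printed}{`X = x' * (z0 / z)`, `Y = y' * (z0 / z)`,
#'     `Z = z / z0`: the literal depth-normalization form, which shrinks
#'     lateral coordinates with distance. Retained for fidelity; the two
#'     conventions coincide exactly when `z == z0` and differ by the factor
#'     `(z0/z)^2` on lateral coordinates otherwise.}
#' }
#'
#' @param track A `camera_track` from [to_camera_view()].
#' @param depth A [depth_track()] covering every frame of `track`.
#' @param convention `"pinhole"` or `"as_printed"`.
#' @return A `world_track`: long data frame with columns `frame`, `t`,
#'   `joint`, `X`, `Y`, `Z`, `quality`; coordinates are unitless multiples
#'   of `z0` (attributes `z0`, `convention`). `Y` keeps the image-down
#'   orientation: larger `Y` is closer to the ground.
#' @export
to_world_view <- function(track, depth,
                          convention = c("pinhole", "as_printed")) {
  convention <- match.arg(convention)
  stopifnot(inherits(track, "camera_track"), inherits(depth, "depth_track"))
  t <- frame_times(track)
  if (length(depth$t) != length(t) ||
      (length(t) > 0 && max(abs(depth$t - t)) > 1e-6)) {
    stop(gait_error("gait_alignment_error",
                    "depth track does not cover the frames of the series"))
  }
  ratio <- depth$z / depth$z0            # z / z0, frames x 25
  fac <- if (convention == "pinhole") ratio else 1 / ratio
  X <- kp_mat(track, "xp") * fac
  Y <- kp_mat(track, "yp") * fac
  out <- .track_df(t, X, Y, kp_mat(track, "quality"),
                   c("X", "Y"), "world_track",
                   list(z0 = depth$z0, convention = convention,
                        nominal_fps = attr(track, "nominal_fps")))
  out$Z <- as.vector(t(ratio))
  out
}

#' Define the virtual walkway
#'
#' The walkway is the augmented-reality construct that anchors metric
#' scale: start and end lines a known distance apart (default 4 m,
#' excluding initial acceleration), subdivided by 10 cm waypoints. Start
#' and end are points in the world-view frame (multiples of `z0`); `scale`
#' converts world units to meters and is fixed by the known marker
#' separation.
#'
#' @param start,end World-frame points (length-3 numeric) of the start and
#'   end line centers.
#' @param length Walkway length in meters (default 4).
#' @param waypoint_spacing Waypoint spacing in meters (default 0.10); must
#'   divide `length`.
#' @param scale Meters per world unit. If `NULL`, inferred as
#'   `length / |end - start|`.
#' @return A `walkway_definition` object.
#' @export
walkway_definition <- function(start, end, length = 4.0,
                               waypoint_spacing = 0.10, scale = NULL) {
  start <- as.numeric(start); end <- as.numeric(end)
  stopifnot(length(start) == 3L, length(end) == 3L)
  d <- sqrt(sum((end - start)^2))
  if (d < 1e-12) {
    stop(gait_error("gait_parameter_error",
                    "degenerate walkway: start equals end"))
  }
  if (is.null(scale)) scale <- length / d
  if (abs(d * scale - length) > 1e-6) {
    stop(gait_error("gait_parameter_error",
                    sprintf("|end - start| * scale = %.8f != length %.8f",
                            d * scale, length)))
  }
  k <- length / waypoint_spacing
  if (abs(k - round(k)) > 1e-9) {
    stop(gait_error("gait_parameter_error",
                    "waypoint_spacing must divide walkway length"))
  }
  structure(list(start = start, end = end, length = length,
                 waypoint_spacing = waypoint_spacing, scale = scale),
            class = "walkway_definition")
}

# unit axes of the walkway in world coordinates: progression u and the
# in-ground-plane lateral axis (orthogonal to u within the X-Z plane; the
# world Y axis is the image-vertical direction).
.walkway_axes <- function(walkway) {
  v <- walkway$end - walkway$start
  u <- v / sqrt(sum(v^2))
  lat <- c(-u[3], 0, u[1])
  nl <- sqrt(sum(lat^2))
  if (nl < 1e-12) {
    stop(gait_error("gait_parameter_error",
                    "walkway axis is vertical; no ground-plane lateral axis"))
  }
  list(u = u, lat = lat / nl)
}

# progression (meters along start->end) for every joint: frames x 25
.progression_matrix <- function(world, walkway) {
  ax <- .walkway_axes(walkway)
  X <- kp_mat(world, "X") - walkway$start[1]
  Y <- kp_mat(world, "Y") - walkway$start[2]
  Z <- kp_mat(world, "Z") - walkway$start[3]
  (X * ax$u[1] + Y * ax$u[2] + Z * ax$u[3]) * walkway$scale
}

# lateral (meters, in ground plane, orthogonal to progression)
.lateral_matrix <- function(world, walkway) {
  ax <- .walkway_axes(walkway)
  X <- kp_mat(world, "X") - walkway$start[1]
  Z <- kp_mat(world, "Z") - walkway$start[3]
  (X * ax$lat[1] + Z * ax$lat[3]) * walkway$scale
}

# vertical height above the walkway plane (meters); world Y is image-down
.height_matrix <- function(world, walkway) {
  (walkway$start[2] - kp_mat(world, "Y")) * walkway$scale
}

#' Progression of a reference joint along the walkway
#'
#' Projects a joint's world-view trajectory onto the start-to-end walkway
#' axis, yielding a per-frame scalar progression in meters: 0 at the start
#' line, `length` at the end line.
#'
#' @param world A `world_track` from [to_world_view()].
#' @param walkway A [walkway_definition()].
#' @param joint Reference joint name (default `"mid_hip"`, the pelvis).
#' @return Numeric vector of per-frame progression (meters), with the
#'   frame times as attribute `"t"`.
#' @export
project_to_walkway_axis <- function(world, walkway, joint = "mid_hip") {
  stopifnot(inherits(world, "world_track"),
            inherits(walkway, "walkway_definition"))
  prog <- .progression_matrix(world, walkway)[, joint]
  attr(prog, "t") <- frame_times(world)
  prog
}
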
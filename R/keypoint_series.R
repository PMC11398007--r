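#' Construct a keypoint series
#'
#' A keypoint series is the standardized screen-view stream emitted by a 2D
#' pose detector: for every video frame and every joint of the 25-entry
#' roster, a record `(joint, x, y, quality, t)`. Coordinates are pixels in
#' the image frame (origin top-left, x rightward, y downward), `quality` is
#' a detector confidence in `[0, 1]` with 0 meaning "missing", and `t` is
#' seconds from recording start.
#'
#' The constructor validates and canonicalizes the input: every frame must
#' contain each roster joint exactly once, timestamps must be strictly
#' increasing, and non-finite coordinates are only allowed where
#' `quality == 0`. Rows are re-ordered frame-major, joints in roster order,
#' which is the layout all downstream matrix accessors assume.
#'
#' @param data A data frame with columns `t`, `joint`, `x`, `y`, `quality`
#'   (and optionally `interpolated`).
#' @param nominal_fps Nominal frame rate in Hz (default 60). If the median
#'   observed frame interval deviates from `1/nominal_fps` by more than 20%
#'   a warning is attached to the result (attribute `"fps_warning"`).
#' @return A `keypoint_series`: a long data frame with columns `frame`, `t`,
#'   `joint`, `x`, `y`, `quality`, `interpolated` and attribute
#'   `nominal_fps`.
#' @export
#' @examples
#' walk <- simulate_walk(walk_spec(speed = 1.0, seed = 1))
#' series <- walk$series
#' nrow(series) / 25  # frames
keypoint_series <- function(data, nominal_fps = 60) {
  required <- c("t", "joint", "x", "y", "quality")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    stop(gait_error("gait_format_error",
                    sprintf("missing required column(s): %s",
                            paste(missing_cols, collapse = ", "))))
  }
  data <- as.data.frame(data)
  data$joint <- as.character(data$joint)
  jid <- joint_id(data$joint)  # errors on unknown names

  if (!("interpolated" %in% names(data))) data$interpolated <- FALSE

  if (any(data$quality < 0 | data$quality > 1, na.rm = TRUE) ||
      anyNA(data$quality)) {
    stop(gait_error("gait_validation_error",
                    "quality must be finite and within [0, 1]"))
  }
  bad_coord <- (!is.finite(data$x) | !is.finite(data$y)) & data$quality > 0
  if (any(bad_coord)) {
    stop(gait_error("gait_validation_error",
                    "non-finite coordinates require quality == 0"))
  }

  times <- sort(unique(data$t))
  if (length(times) > 1 && any(diff(times) <= 0)) {
    stop(gait_error("gait_validation_error",
                    "timestamps must be strictly increasing"))
  }
  # frames are identified by timestamp; check per-frame completeness
  data$frame <- match(data$t, times)
  n_frames <- length(times)
  if (nrow(data) != n_frames * 25L) {
    stop(gait_error("gait_validation_error",
                    sprintf(
                      "expected %d keypoints (25 per frame), got %d",
                      n_frames * 25L, nrow(data))))
  }
  key <- data$frame * 25L + jid
  if (anyDuplicated(key)) {
    stop(gait_error("gait_validation_error",
                    "duplicate joint within a frame"))
  }

  ord <- order(data$frame, jid)
  out <- data[ord, c("frame", "t", "joint", "x", "y",
                     "quality", "interpolated")]
  rownames(out) <- NULL
  # explicit monotonicity check on the per-frame timestamps
  ft <- out$t[seq(1, nrow(out), by = 25L)]
  if (length(ft) > 1 && any(diff(ft) <= 0)) {
    stop(gait_error("gait_validation_error",
                    "timestamps must be strictly increasing"))
  }

  attr(out, "nominal_fps") <- nominal_fps
  if (length(ft) > 1) {
    med_dt <- stats::median(diff(ft))
    if (abs(med_dt - 1 / nominal_fps) > 0.2 / nominal_fps) {
      attr(out, "fps_warning") <- sprintf(
        "median frame interval %.4fs deviates >20%% from nominal 1/%g s",
        med_dt, nominal_fps)
    }
  }
  class(out) <- c("keypoint_series", "data.frame")
  out
}

# Fast constructor from frame-by-joint matrices (internal; used by the
# simulator and interpolation where validity is guaranteed by construction).
series_from_mats <- function(t, x, y, quality, nominal_fps = 60,
                             interpolated = NULL) {
  n <- length(t)
  stopifnot(is.matrix(x), is.matrix(y), is.matrix(quality),
            nrow(x) == n, ncol(x) == 25L,
            all(dim(y) == dim(x)), all(dim(quality) == dim(x)))
  if (is.null(interpolated)) {
    interp <- rep(FALSE, n * 25L)
  } else {
    interp <- as.vector(t(interpolated))
  }
  out <- data.frame(
    frame = rep(seq_len(n), each = 25L),
    t = rep(t, each = 25L),
    joint = rep(.joint_table$name, times = n),
    x = as.vector(t(x)),
    y = as.vector(t(y)),
    quality = as.vector(t(quality)),
    interpolated = interp,
    stringsAsFactors = FALSE
  )
  attr(out, "nominal_fps") <- nominal_fps
  class(out) <- c("keypoint_series", "data.frame")
  out
}

#' Number of frames in a series or track
#'
#' @param x A `keypoint_series`, `camera_track` or `world_track`.
#' @return Integer frame count.
#' @export
n_frames <- function(x) {
  nrow(x) %/% 25L
}

#' Per-frame timestamps of a series or track
#'
#' @inheritParams n_frames
#' @return Numeric vector of frame times in seconds.
#' @export
frame_times <- function(x) {
  x$t[seq(1L, nrow(x), by = 25L)]
}

# Extract one field as a frames x 25 matrix (columns in roster order).
kp_mat <- function(x, field) {
  m <- matrix(x[[field]], ncol = 25L, byrow = TRUE)
  colnames(m) <- .joint_table$name
  m
}

#' @export
print.keypoint_series <- function(x, ...) {
  cat(sprintf(
    "<keypoint_series> %d frames x 25 joints, nominal %g fps, %.2f s\n",
    n_frames(x), attr(x, "nominal_fps"),
    if (nrow(x) > 0) diff(range(x$t)) else 0))
  if (!is.null(attr(x, "fps_warning"))) {
    cat("  warning:", attr(x, "fps_warning"), "\n")
  }
  miss <- sum(x$quality == 0)
  if (miss > 0) cat(sprintf("  %d missing keypoints (quality 0)\n", miss))
  invisible(x)
}

#' Interpolate short gaps of missing keypoints
#'
#' Real pose detectors drop joints for a few frames at a time. Missingness
#' is encoded as `quality == 0`; this fills gaps of at most
#' `max_gap_frames` consecutive missing frames per joint by linear
#' interpolation in time between the bracketing observed keypoints, and
#' tags the filled rows `interpolated = TRUE`. Longer gaps, and gaps
#' touching either end of the recording, are left missing. Keypoints with
#' `quality > 0` are never altered.
#'
#' @param series A `keypoint_series`.
#' @param max_gap_frames Maximum gap length (frames) to fill; default 3
#'   (50 ms at 60 fps), a deliberately conservative choice.
#' @return A `keypoint_series` with short gaps filled. Filled keypoints get
#'   the smaller of the two bracketing quality values.
#' @export
fill_missing <- function(series, max_gap_frames = 3) {
  stopifnot(inherits(series, "keypoint_series"), max_gap_frames >= 0)
  n <- n_frames(series)
  if (n == 0 || max_gap_frames == 0) return(series)
  t <- frame_times(series)
  x <- kp_mat(series, "x"); y <- kp_mat(series, "y")
  q <- kp_mat(series, "quality")
  interp <- matrix(series$interpolated, ncol = 25L, byrow = TRUE)

  for (j in seq_len(25L)) {
    miss <- q[, j] == 0
    if (!any(miss) || all(miss)) next
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values)) {
      len <- r$lengths[k]
      lo <- starts[k] - 1L
      hi <- ends[k] + 1L
      if (len > max_gap_frames || lo < 1L || hi > n) next
      idx <- starts[k]:ends[k]
      w <- (t[idx] - t[lo]) / (t[hi] - t[lo])
      x[idx, j] <- x[lo, j] + w * (x[hi, j] - x[lo, j])
      y[idx, j] <- y[lo, j] + w * (y[hi, j] - y[lo, j])
      q[idx, j] <- min(q[lo, j], q[hi, j])
      interp[idx, j] <- TRUE
    }
  }
  out <- series_from_mats(t, x, y, q,
                          nominal_fps = attr(series, "nominal_fps"),
                          interpolated = interp)
  attr(out, "fps_warning") <- attr(series, "fps_warning")
  out
}
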
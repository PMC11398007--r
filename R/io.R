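#' Read and write keypoint series files
#'
#' Two plain-text dialects are supported:
#' \describe{
#'   \item{jsonl}{One frame per line:
#'     `{"t": <seconds>, "kp": [[<joint>, <x>, <y>, <quality>], ... x 25]}`.
#'     Missing keypoints carry `null` coordinates and quality 0.}
#'   \item{csv}{Long format with mandatory header `t,joint,x,y,quality`;
#'     one row per keypoint, 25 rows per frame.}
#' }
#' Coordinates are written with six decimal places, so a write/read round
#' trip reproduces the series to 1e-6 px.
#'
#' @param path File path.
#' @param dialect `"jsonl"` or `"csv"`.
#' @param nominal_fps Nominal frame rate attached to the returned series.
#' @return `read_keypoint_series()`: a validated [keypoint_series()].
#'   Malformed lines are rejected with their line number.
#' @export
read_keypoint_series <- function(path, dialect = c("jsonl", "csv"),
                                 nominal_fps = 60) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) {
    stop(gait_error("gait_io_error", sprintf("file not found: %s", path)))
  }
  if (dialect == "csv") {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE),
      error = function(e) {
        stop(gait_error("gait_format_error",
                        sprintf("cannot parse CSV %s: %s",
                                path, conditionMessage(e))))
      })
    required <- c("t", "joint", "x", "y", "quality")
    if (!all(required %in% names(df))) {
      stop(gait_error("gait_format_error",
                      sprintf("missing required column(s): %s",
                              paste(setdiff(required, names(df)),
                                    collapse = ", "))))
    }
    if (nrow(df) == 0) {
      return(series_from_mats(numeric(0),
                              matrix(numeric(0), 0, 25),
                              matrix(numeric(0), 0, 25),
                              matrix(numeric(0), 0, 25),
                              nominal_fps = nominal_fps))
    }
    return(keypoint_series(df, nominal_fps = nominal_fps))
  }

  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(series_from_mats(numeric(0),
                            matrix(numeric(0), 0, 25),
                            matrix(numeric(0), 0, 25),
                            matrix(numeric(0), 0, 25),
                            nominal_fps = nominal_fps))
  }
  n <- length(lines)
  t <- numeric(n)
  x <- matrix(NA_real_, n, 25L)
  y <- matrix(NA_real_, n, 25L)
  q <- matrix(NA_real_, n, 25L)
  for (i in seq_len(n)) {
    rec <- tryCatch(
      jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
      error = function(e) {
        stop(gait_error("gait_format_error",
                        sprintf("line %d: invalid JSON (%s)",
                                i, conditionMessage(e))))
      })
    if (is.null(rec$t) || is.null(rec$kp) || length(rec$kp) != 25L) {
      stop(gait_error("gait_format_error",
                      sprintf("line %d: frame must carry t and 25 keypoints",
                              i)))
    }
    t[i] <- as.numeric(rec$t)
    for (kp in rec$kp) {
      if (length(kp) != 4L) {
        stop(gait_error("gait_format_error",
                        sprintf("line %d: keypoint must be [joint,x,y,quality]",
                                i)))
      }
      jname <- as.character(kp[[1]])
      j <- tryCatch(joint_id(jname), error = function(e) {
        stop(gait_error("gait_validation_error",
                        sprintf("line %d: unknown joint name '%s'", i, jname)))
      })
      col <- j + 1L
      if (!is.na(q[i, col])) {
        stop(gait_error("gait_validation_error",
                        sprintf("line %d: duplicate joint '%s'", i, jname)))
      }
      x[i, col] <- if (is.null(kp[[2]])) NA_real_ else as.numeric(kp[[2]])
      y[i, col] <- if (is.null(kp[[3]])) NA_real_ else as.numeric(kp[[3]])
      q[i, col] <- as.numeric(kp[[4]])
    }
    if (anyNA(q[i, ])) {
      miss <- .joint_table$name[is.na(q[i, ])]
      stop(gait_error("gait_validation_error",
                      sprintf("line %d: missing joint(s) %s",
                              i, paste(miss, collapse = ", "))))
    }
  }
  if (length(t) > 1 && any(diff(t) <= 0)) {
    stop(gait_error("gait_validation_error",
                    "timestamps must be strictly increasing"))
  }
  series <- series_from_mats(t, x, y, q, nominal_fps = nominal_fps)
  # route through the validating constructor for quality/finiteness checks
  keypoint_series(series, nominal_fps = nominal_fps)
}

.fmt6 <- function(v) {
  out <- sprintf("%.6f", v)
  out[!is.finite(v)] <- "null"
  out
}

#' @rdname read_keypoint_series
#' @param series A [keypoint_series()] to write.
#' @return `write_keypoint_series()`: the path, invisibly.
#' @export
write_keypoint_series <- function(series, path, dialect = c("jsonl", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(series, "keypoint_series"))
  if (dialect == "csv") {
    df <- data.frame(t = .fmt6(series$t), joint = series$joint,
                     x = .fmt6(series$x), y = .fmt6(series$y),
                     quality = .fmt6(series$quality),
                     stringsAsFactors = FALSE)
    df$x[df$x == "null"] <- NA
    df$y[df$y == "null"] <- NA
    ok <- tryCatch({
      utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) stop(gait_error("gait_io_error",
                             sprintf("cannot write %s", path)))
    return(invisible(path))
  }
  n <- n_frames(series)
  lines <- character(n)
  if (n > 0) {
    t <- frame_times(series)
    x <- kp_mat(series, "x"); y <- kp_mat(series, "y")
    q <- kp_mat(series, "quality")
    jnames <- .joint_table$name
    for (i in seq_len(n)) {
      kp <- sprintf('["%s",%s,%s,%s]', jnames,
                    .fmt6(x[i, ]), .fmt6(y[i, ]), .fmt6(q[i, ]))
      lines[i] <- sprintf('{"t":%s,"kp":[%s]}', .fmt6(t[i]),
                          paste(kp, collapse = ","))
    }
  }
  ok <- tryCatch({
    writeLines(lines, path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop(gait_error("gait_io_error", sprintf("cannot write %s", path)))
  invisible(path)
}

#' Read and write the camera/depth sidecar
#'
#' A recording's calibration travels in a JSON sidecar next to the keypoint
#' file: camera intrinsics, the reference depth `z0`, per-frame (or
#' per-joint) depth samples, and the walkway geometry in world coordinates.
#'
#' @param path Sidecar JSON path.
#' @return `read_sidecar()`: a list with elements `camera`
#'   ([camera_intrinsics()]), `depth` ([depth_track()]) and `walkway`
#'   ([walkway_definition()]).
#' @export
read_sidecar <- function(path) {
  if (!file.exists(path)) {
    stop(gait_error("gait_io_error", sprintf("file not found: %s", path)))
  }
  s <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  cam <- camera_intrinsics(s$fx, s$fy, s$cx, s$cy)
  z <- s$depth$z
  if (is.list(z)) z <- do.call(rbind, z)
  depth <- depth_track(t = s$depth$t, z = z, z0 = s$z0)
  walkway <- walkway_definition(start = s$walkway$start, end = s$walkway$end,
                                length = s$walkway$length,
                                waypoint_spacing = s$walkway$waypoint_spacing,
                                scale = s$walkway$scale)
  list(camera = cam, depth = depth, walkway = walkway)
}

#' @rdname read_sidecar
#' @param camera A [camera_intrinsics()].
#' @param depth A [depth_track()].
#' @param walkway A [walkway_definition()].
#' @export
write_sidecar <- function(camera, depth, walkway, path) {
  obj <- list(
    fx = camera$fx, fy = camera$fy, cx = camera$cx, cy = camera$cy,
    z0 = depth$z0,
    depth = list(t = depth$t, z = depth$z),
    walkway = list(start = walkway$start, end = walkway$end,
                   length = walkway$length,
                   waypoint_spacing = walkway$waypoint_spacing,
                   scale = walkway$scale)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
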
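# Fixed 25-joint skeleton vocabulary. The whole-body roster is
# artifact-defined: head/trunk landmarks plus left/right limb chains down to
# the foot (heel, big toe, small toe), matching what full-body 2D pose
# detectors emit. Ids are 0-based to match common pose-estimation output.
.joint_table <- data.frame(
  id = 0:24,
  name = c(
    "nose", "head", "neck", "sternum", "mid_hip",
    "l_shoulder", "r_shoulder", "l_elbow", "r_elbow",
    "l_wrist", "r_wrist",
    "l_hip", "r_hip", "l_knee", "r_knee", "l_ankle", "r_ankle",
    "l_heel", "r_heel", "l_big_toe", "r_big_toe",
    "l_small_toe", "r_small_toe", "l_ear", "r_ear"
  ),
  stringsAsFactors = FALSE
)

#' The 25-joint skeleton roster
#'
#' Returns the fixed joint vocabulary used throughout the package, in
#' canonical id order (ids 0--24). Every keypoint frame carries exactly one
#' keypoint per roster entry; missing detections are encoded as quality 0,
#' never as absent rows.
#'
#' @return Character vector of 25 joint names, named by their integer ids.
#' @export
#' @examples
#' joint_names()
joint_names <- function() {
  stats::setNames(.joint_table$name, .joint_table$id)
}

#' @rdname joint_names
#' @param name Joint name(s) from the roster.
#' @return `joint_id()`: integer id(s) in `[0, 24]`.
#' @export
joint_id <- function(name) {
  idx <- match(name, .joint_table$name)
  if (anyNA(idx)) {
    bad <- unique(name[is.na(idx)])
    stop(gait_error("gait_validation_error",
                    sprintf("unknown joint name(s): %s",
                            paste(bad, collapse = ", "))))
  }
  .joint_table$id[idx]
}

#' @rdname joint_names
#' @param id Integer joint id(s) in `[0, 24]`.
#' @return `joint_name()`: joint name(s).
#' @export
joint_name <- function(id) {
  idx <- match(id, .joint_table$id)
  if (anyNA(idx)) {
    stop(gait_error("gait_validation_error",
                    sprintf("joint id out of range: %s",
                            paste(unique(id[is.na(idx)]), collapse = ", "))))
  }
  .joint_table$name[idx]
}

# Left/right helper used by event detection and kinematics.
.side_joint <- function(joint, side) {
  stopifnot(side %in% c("LEFT", "RIGHT"))
  paste0(if (side == "LEFT") "l_" else "r_", joint)
}

# Structured condition constructor; every package error carries a class so
# the CLI can map error families to exit codes.
gait_error <- function(class, message, ...) {
  structure(
    class = c(class, "gait_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

gait_warning <- function(class, message, ...) {
  structure(
    class = c(class, "gait_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}
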
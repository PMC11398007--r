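#' Specification of a simulated walk
#'
#' Parameterizes the articulated walker used to generate synthetic
#' keypoint streams with analytic ground truth. The walker is a planar
#' sagittal model: the pelvis advances at constant speed along the
#' walkway, feet alternate between ground-anchored stance (zero
#' progression velocity) and constant-velocity swing, knees follow from
#' two-link inverse kinematics, and the trunk, head and arms ride on the
#' pelvis with phase-locked sway. The scene is viewed side-on through a
#' pinhole camera and projected to pixels, after which Gaussian pixel
#' noise and per-joint quality scores (with optional dropout) are applied.
#'
#' Speed, cadence and stride length are tied by
#' `speed = stride_length * cadence / 120`; supply any two (or just
#' `speed`, in which case cadence follows the affine rule
#' `cadence = 75 + 35 * speed`, giving roughly 96--124 steps/min over the
#' supported speed range).
#'
#' @param speed Walking speed in m/s (0.5--2.0).
#' @param cadence Steps per minute; default derived from `speed`.
#' @param stride_length Stride length in m; default derived.
#' @param stance_fraction Fraction of the gait cycle in stance, in
#'   (0.5, 0.75); default 0.6.
#' @param step_width Mediolateral distance between the feet (m),
#'   default 0.10.
#' @param subject_height Subject height in m, default 1.70.
#' @param start_offset Standing position, in m before the start line
#'   (default 1.0, so the walkway excludes gait initiation).
#' @param walkway_length Walkway length in m (default 4).
#' @param camera A [camera_intrinsics()]; default models a 1080p phone
#'   camera (fx = fy = 700 px, principal point at image center).
#' @param camera_distance Perpendicular distance from camera to walkway
#'   midline (m), default 4. Also the reference depth `z0`.
#' @param camera_height Camera height above the ground (m), default 1.4.
#' @param pixel_noise_sd Gaussian keypoint noise, pixels (default 0).
#' @param quality_baseline,quality_sd Mean and sd of per-keypoint quality
#'   scores (clamped to (0, 1]).
#' @param dropout_prob Independent per-keypoint probability of a missed
#'   detection (quality 0, coordinates dropped).
#' @param fps Frame rate, default 60.
#' @param onset_time Seconds of still standing before gait starts
#'   (default 1.0); `command_time` is when the (virtual) start command is
#'   given (default 0.5), so the true reaction time is
#'   `onset_time - command_time`.
#' @param command_time See `onset_time`.
#' @param overshoot Meters walked past the end line (default 0.5).
#' @param heel_rise_phase Cycle fraction at which the heel leaves the
#'   ground (default 0.4; must be below `stance_fraction`).
#' @param seed Integer seed governing all simulated randomness.
#' @return A validated `walk_spec` object.
#' @export
walk_spec <- function(speed = 1.0, cadence = NULL, stride_length = NULL,
                      stance_fraction = 0.6, step_width = 0.10,
                      subject_height = 1.70, start_offset = 1.0,
                      walkway_length = 4.0,
                      camera = camera_intrinsics(700, 700, 960, 540),
                      camera_distance = 4.0, camera_height = 1.4,
                      pixel_noise_sd = 0, quality_baseline = 0.9,
                      quality_sd = 0.05, dropout_prob = 0,
                      fps = 60, onset_time = 1.0, command_time = 0.5,
                      overshoot = 0.5, heel_rise_phase = 0.4, seed = 1L) {
  if (is.null(cadence) && is.null(stride_length)) {
    cadence <- 75 + 35 * speed
  }
  if (is.null(stride_length)) stride_length <- 120 * speed / cadence
  if (is.null(cadence)) cadence <- 120 * speed / stride_length
  if (abs(speed - stride_length * cadence / 120) > 1e-6) {
    stop(gait_error("gait_specification_error",
                    "speed, cadence and stride_length are inconsistent"))
  }
  if (speed < 0.5 || speed > 2.0) {
    stop(gait_error("gait_specification_error",
                    "speed must be within 0.5-2.0 m/s"))
  }
  if (stance_fraction <= 0.5 || stance_fraction >= 0.75) {
    stop(gait_error("gait_specification_error",
                    "stance_fraction must be in (0.5, 0.75)"))
  }
  if (heel_rise_phase >= stance_fraction || heel_rise_phase <= 0) {
    stop(gait_error("gait_specification_error",
                    "heel_rise_phase must lie inside the stance phase"))
  }
  structure(list(
    speed = speed, cadence = cadence, stride_length = stride_length,
    stance_fraction = stance_fraction, step_width = step_width,
    subject_height = subject_height, start_offset = start_offset,
    walkway_length = walkway_length, camera = camera,
    camera_distance = camera_distance, camera_height = camera_height,
    pixel_noise_sd = pixel_noise_sd, quality_baseline = quality_baseline,
    quality_sd = quality_sd, dropout_prob = dropout_prob, fps = fps,
    onset_time = onset_time, command_time = command_time,
    overshoot = overshoot, heel_rise_phase = heel_rise_phase,
    seed = as.integer(seed)
  ), class = "walk_spec")
}

# --- continuous walker model ------------------------------------------------
# All functions take tau = time since gait onset (clamped at 0 while the
# subject stands) and return meters in the scene frame: x progression
# (0 at the start line), y height above ground, z depth from the camera.

.cycle_state <- function(tau, spec, offset_cycles) {
  T <- 120 / spec$cadence
  tc <- pmax(0, tau)
  phi <- tc / T + offset_cycles
  n <- floor(phi)
  u <- phi - n
  list(T = T, tc = tc, n = n, u = u)
}

.pelvis_x <- function(tau, spec) {
  -spec$start_offset + spec$speed * pmax(0, tau)
}

# heel-strike placement position of cycle k for a foot with the given
# half-cycle offset
.placement <- function(k, spec, offset_cycles) {
  T <- 120 / spec$cadence
  -spec$start_offset +
    spec$speed * pmax(0, (k - offset_cycles + spec$stance_fraction / 2) * T)
}

.foot_x <- function(tau, spec, offset_cycles) {
  st <- .cycle_state(tau, spec, offset_cycles)
  sf <- spec$stance_fraction
  p0 <- .placement(st$n, spec, offset_cycles)
  p1 <- .placement(st$n + 1, spec, offset_cycles)
  ifelse(st$u < sf, p0, p0 + (p1 - p0) * (st$u - sf) / (1 - sf))
}

.toe_y <- function(u, spec) {
  0.04 * (1 - cos(2 * pi * (u - spec$stance_fraction))) / 2
}

.heel_y <- function(u, spec) {
  hr <- spec$heel_rise_phase
  ifelse(u <= hr, 0, 0.12 * sin(pi * (u - hr) / (1 - hr)))
}

.ankle_y <- function(u, spec) {
  0.05 + 0.5 * .heel_y(u, spec)
}

# two-link inverse kinematics for the knee in the sagittal plane;
# the knee bows forward (positive progression offset) as in human gait
.knee_ik <- function(hx, hy, ax, ay, L1, L2) {
  dx <- ax - hx; dy <- ay - hy
  d <- sqrt(dx^2 + dy^2)
  dmax <- L1 + L2 - 1e-9
  dc <- pmin(d, dmax)
  a <- (L1^2 - L2^2 + dc^2) / (2 * dc)
  hseg <- sqrt(pmax(0, L1^2 - a^2))
  ux <- dx / d; uy <- dy / d
  px <- -uy; py <- ux
  flip <- px < 0
  px[flip] <- -px[flip]; py[flip] <- -py[flip]
  list(x = hx + a * ux + hseg * px, y = hy + a * uy + hseg * py)
}

# full scene state at the given taus: 25-joint x/y/z matrices (meters)
# plus true knee angles per side
.walker_positions <- function(tau, spec) {
  nt <- length(tau)
  h <- spec$subject_height
  D <- spec$camera_distance
  w <- spec$step_width
  H_hip <- 0.516 * h          # pelvis rides just below full leg length
  L1 <- 0.245 * h; L2 <- 0.245 * h
  px <- .pelvis_x(tau, spec)

  X <- matrix(NA_real_, nt, 25L); Y <- X; Z <- X
  colnames(X) <- .joint_table$name
  colnames(Y) <- .joint_table$name
  colnames(Z) <- .joint_table$name

  set_j <- function(name, x, y, z) {
    X[, name] <<- x; Y[, name] <<- y; Z[, name] <<- rep(z, length.out = nt)
  }

  set_j("mid_hip", px, H_hip, D)
  set_j("sternum", px, 0.72 * h, D)
  set_j("neck", px, 0.80 * h, D)
  set_j("nose", px + 0.03, 0.86 * h, D)
  set_j("head", px, 0.92 * h, D)

  knee_angles <- list()
  for (side in c("LEFT", "RIGHT")) {
    off <- if (side == "RIGHT") 0 else 0.5
    sgn <- if (side == "RIGHT") 1 else -1
    zf <- D + sgn * w / 2
    st <- .cycle_state(tau, spec, off)
    fx <- .foot_x(tau, spec, off)
    ay <- .ankle_y(st$u, spec)
    hy <- .heel_y(st$u, spec)
    ty <- .toe_y(st$u, spec)

    set_j(.side_joint("ankle", side), fx, ay, zf)
    set_j(.side_joint("heel", side), fx - 0.06, hy, zf)
    set_j(.side_joint("big_toe", side), fx + 0.12, ty, zf)
    set_j(.side_joint("small_toe", side), fx + 0.10, ty, zf + sgn * 0.02)
    set_j(.side_joint("hip", side), px, H_hip, D + sgn * 0.05)

    kn <- .knee_ik(px, rep(H_hip, nt), fx, ay, L1, L2)
    set_j(.side_joint("knee", side), kn$x, kn$y, (D + zf) / 2)
    knee_angles[[side]] <- .angle_deg(px, rep(H_hip, nt),
                                      kn$x, kn$y, fx, ay)

    # arm swings in antiphase with the ipsilateral leg
    alpha <- 0.3 * sin(2 * pi * (st$tc / st$T + off + 0.5))
    shx <- px; shy <- rep(0.79 * h, nt); shz <- D + sgn * 0.11
    set_j(.side_joint("shoulder", side), shx, shy, shz)
    ex <- shx + 0.17 * h * sin(alpha); ey <- shy - 0.17 * h * cos(alpha)
    set_j(.side_joint("elbow", side), ex, ey, shz)
    set_j(.side_joint("wrist", side),
          ex + 0.15 * h * sin(1.3 * alpha),
          ey - 0.15 * h * cos(1.3 * alpha), shz)
    set_j(.side_joint("ear", side), px, 0.86 * h, D + sgn * 0.07)
  }
  list(x = X, y = Y, z = Z, knee_angles = knee_angles)
}

# analytic ground-truth event times over (0, dur]
.truth_events <- function(spec, dur) {
  T <- 120 / spec$cadence
  sf <- spec$stance_fraction
  hr <- spec$heel_rise_phase
  onset <- spec$onset_time
  rows <- list()
  add <- function(type, side, taus) {
    taus <- taus[taus > 1e-9 & onset + taus <= dur]
    if (length(taus) == 0) return()
    rows[[length(rows) + 1]] <<- data.frame(
      type = type, side = side, t = onset + taus, stringsAsFactors = FALSE)
  }
  kmax <- ceiling(dur / T) + 2
  for (side in c("LEFT", "RIGHT")) {
    off <- if (side == "RIGHT") 0 else 0.5
    k <- 0:kmax
    add("HEEL_STRIKE", side, (k - off) * T)
    add("TOE_OFF", side, (k + sf - off) * T)
    add("HEEL_RISE", side, (k + hr - off) * T)
    # feet adjacent: the swinging foot passes the stance foot; solved on
    # the continuous model because gait-initiation cycles are asymmetric
    other <- if (side == "RIGHT") 0.5 else 0
    dfeet <- function(tau) {
      .foot_x(tau, spec, off) - .foot_x(tau, spec, other)
    }
    fa <- c()
    for (kk in k) {
      lo <- (kk + sf - off) * T + 1e-6
      hi <- (kk + 1 - off) * T - 1e-6
      if (hi <= lo || lo < 0 || onset + lo > dur) next
      hi <- min(hi, dur - onset)
      if (hi <= lo) next
      dlo <- dfeet(lo); dhi <- dfeet(hi)
      if (!is.finite(dlo) || !is.finite(dhi) || dlo * dhi > 0) next
      fa <- c(fa, stats::uniroot(dfeet, c(lo, hi), tol = 1e-8)$root)
    }
    add("FEET_ADJACENT", side, fa)
    # tibia vertical: root of knee - ankle progression inside each stance
    g <- function(tau) {
      p <- .walker_positions(tau, spec)
      p$x[1, .side_joint("knee", side)] - p$x[1, .side_joint("ankle", side)]
    }
    tv <- c()
    for (kk in k) {
      lo <- max(1e-6, (kk - off) * T)
      hi <- (kk + sf - off) * T
      if (hi <= lo || onset + lo > dur) next
      hi <- min(hi - 1e-6, dur - onset)
      if (hi <= lo) next
      glo <- g(lo); ghi <- g(hi)
      if (!is.finite(glo) || !is.finite(ghi) || glo * ghi > 0) next
      tv <- c(tv, stats::uniroot(g, c(lo, hi), tol = 1e-8)$root)
    }
    add("TIBIA_VERTICAL", side, tv)
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$t), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Simulate a walk with full ground truth
#'
#' Runs the articulated-walker model of [walk_spec()] over a complete
#' recording (standing, gait onset, walkway traversal, overshoot),
#' projects every joint through the pinhole camera at its per-frame depth,
#' and applies seeded Gaussian pixel noise and quality dropout. All
#' ground-truth quantities are emitted analytically from the model, never
#' re-detected from the generated data.
#'
#' @param spec A [walk_spec()].
#' @return A `simulated_walk` list:
#' \describe{
#'   \item{series}{[keypoint_series()] in screen coordinates.}
#'   \item{depth}{[depth_track()] of per-joint depths (`z0` = camera
#'     distance).}
#'   \item{walkway}{[walkway_definition()] in the world frame.}
#'   \item{camera}{the [camera_intrinsics()].}
#'   \item{truth}{list with true `speed`, `stride_length`, `step_length`,
#'     `cadence`, `stance_fraction`, `step_width`, crossing times, event
#'     table, `step_count`, onset/command/reaction/ignition times, and
#'     true knee-angle traces.}
#' }
#' @export
#' @examples
#' walk <- simulate_walk(walk_spec(speed = 1.2, seed = 7))
#' walk$truth$speed
simulate_walk <- function(spec) {
  stopifnot(inherits(spec, "walk_spec"))
  v <- spec$speed
  dur <- spec$onset_time +
    (spec$start_offset + spec$walkway_length + spec$overshoot) / v
  t <- seq(0, dur, by = 1 / spec$fps)
  tau <- t - spec$onset_time

  pos <- .walker_positions(tau, spec)
  cam <- spec$camera
  cam_x <- spec$walkway_length / 2   # camera centered on the walkway
  z0 <- spec$camera_distance

  px <- cam$cx + cam$fx * (pos$x - cam_x) / pos$z
  py <- cam$cy + cam$fy * (spec$camera_height - pos$y) / pos$z

  n <- length(t)
  q <- matrix(spec$quality_baseline, n, 25L)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  if (spec$pixel_noise_sd > 0) {
    px <- px + matrix(stats::rnorm(n * 25L, 0, spec$pixel_noise_sd), n, 25L)
    py <- py + matrix(stats::rnorm(n * 25L, 0, spec$pixel_noise_sd), n, 25L)
  }
  q <- matrix(stats::rnorm(n * 25L, spec$quality_baseline, spec$quality_sd),
              n, 25L)
  q <- pmin(pmax(q, 0.01), 1)  # keeps dim() (matrix first argument)
  if (spec$dropout_prob > 0) {
    drop <- matrix(stats::runif(n * 25L) < spec$dropout_prob, n, 25L)
    q[drop] <- 0
    px[drop] <- NA_real_
    py[drop] <- NA_real_
  }

  series <- series_from_mats(t, px, py, q, nominal_fps = spec$fps)
  depth <- depth_track(t, pos$z, z0 = z0)
  walkway <- walkway_definition(
    start = c((0 - cam_x) / z0, spec$camera_height / z0, z0 / z0),
    end = c((spec$walkway_length - cam_x) / z0, spec$camera_height / z0, 1),
    length = spec$walkway_length, scale = z0)

  t_cs <- spec$onset_time + spec$start_offset / v
  t_ce <- spec$onset_time + (spec$start_offset + spec$walkway_length) / v
  events <- .truth_events(spec, dur)
  hs_in <- events$type == "HEEL_STRIKE" &
    events$t >= t_cs & events$t <= t_ce

  truth <- list(
    speed = v,
    stride_length = spec$stride_length,
    step_length = spec$stride_length / 2,
    cadence = spec$cadence,
    stance_fraction = spec$stance_fraction,
    step_width = spec$step_width,
    t_cross_start = t_cs,
    t_cross_end = t_ce,
    walk_time = spec$walkway_length / v,
    events = events,
    step_count = sum(hs_in),
    movement_onset = spec$onset_time,
    command_time = spec$command_time,
    reaction_time = spec$onset_time - spec$command_time,
    ignition_time = spec$start_offset / v,
    knee_angle_left = pos$knee_angles$LEFT,
    knee_angle_right = pos$knee_angles$RIGHT,
    t = t
  )
  structure(list(series = series, depth = depth, walkway = walkway,
                 camera = cam, truth = truth, spec = spec),
            class = "simulated_walk")
}

#' Simulate a cohort of walks
#'
#' Draws `n` walking speeds uniformly from `speed_range` (seeded),
#' derives cadence from each speed via the affine rule of [walk_spec()],
#' and simulates each walk with an independently derived seed. The result
#' pairs every walk with its ground truth, ready for agreement analysis
#' against pipeline estimates.
#'
#' @param n Number of walks.
#' @param speed_range Length-2 numeric, m/s.
#' @param noise_sd Pixel noise sd applied to every walk.
#' @param dropout_prob Per-keypoint dropout probability.
#' @param seed Master seed; the whole cohort is reproducible from it.
#' @param ... Further arguments passed to [walk_spec()].
#' @return A `simulated_cohort`: list of `simulated_walk` objects.
#' @export
simulate_cohort <- function(n, speed_range, noise_sd = 2,
                            dropout_prob = 0.01, seed = 1L, ...) {
  if (n < 1) {
    stop(gait_error("gait_specification_error", "n must be >= 1"))
  }
  if (length(speed_range) != 2 || speed_range[2] < speed_range[1]) {
    stop(gait_error("gait_specification_error",
                    "speed_range must be an increasing length-2 numeric"))
  }
  if (n == 1) {
    warning(gait_warning("gait_degenerate_input",
                         "cohort of size 1: downstream statistics degenerate"))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  speeds <- stats::runif(n, speed_range[1], speed_range[2])
  walk_seeds <- sample.int(2^30, n)
  if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                 envir = globalenv())
  walks <- vector("list", n)
  for (i in seq_len(n)) {
    spec <- walk_spec(speed = speeds[i], pixel_noise_sd = noise_sd,
                      dropout_prob = dropout_prob, seed = walk_seeds[i], ...)
    walks[[i]] <- simulate_walk(spec)
  }
  structure(walks, class = "simulated_cohort")
}
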
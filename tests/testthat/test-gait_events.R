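test_that("troughs of a pure sine land on its analytic minima", {
  t <- seq(0, 3, by = 1 / 60)
  y <- sin(2 * pi * t)
  tr <- detect_troughs(y, t)
  expect_length(tr, 3)
  expect_lt(match_events(c(0.75, 1.75, 2.75), t[tr]), 1 + 1e-9)
})

test_that("constant signals yield no troughs", {
  t <- seq(0, 2, by = 1 / 60)
  expect_identical(detect_troughs(rep(4.2, length(t)), t), integer(0))
  expect_error(detect_troughs(c(1, 2), c(0, 1)), class = "gait_length_error")
})

test_that("noisy sine keeps the trough count with <= 2-frame shifts", {
  set.seed(31)
  t <- seq(0, 3, by = 1 / 60)
  y <- sin(2 * pi * t) + rnorm(length(t), sd = 0.05)
  tr <- detect_troughs(y, t)
  expect_length(tr, 3)
  expect_lt(match_events(c(0.75, 1.75, 2.75), t[tr]), 2 + 1e-9)
})

test_that("troughs of -f are the peaks of f (reflection duality) and
          match a brute-force scan", {
  set.seed(5)
  for (k in 1:5) {
    t <- seq(0, 2.5, by = 1 / 60)
    y <- sin(2 * pi * (t + runif(1))) + 0.3 * cos(4 * pi * t)
    pol <- trough_policy(local_mean_window = 1,
                         prominence_fraction = 0.05,
                         min_separation = 1 / 120)
    tr <- detect_troughs(-y, t, pol)
    # brute force: all strict interior local maxima of y
    brute <- which(diff(sign(diff(y))) == -2) + 1
    expect_true(all(tr %in% brute))
    # major maxima (prominence above half the range) are all recovered
    p2p <- diff(range(y))
    major <- brute[vapply(brute, function(i) {
      y[i] - max(min(y[1:i]), min(y[i:length(y)])) > 0.5 * p2p
    }, logical(1))]
    expect_true(all(major %in% tr))
  }
})

test_that("trough detection is invariant to time shift and vertical
          offset", {
  set.seed(13)
  t <- seq(0, 3, by = 1 / 60)
  y <- sin(2 * pi * t) + rnorm(length(t), sd = 0.02)
  base <- detect_troughs(y, t)
  expect_identical(detect_troughs(y + 17.3, t), base)
  expect_identical(detect_troughs(y, t + 100), base)
})

test_that("min_separation keeps the deeper of two close troughs", {
  t <- seq(0, 1, by = 1 / 60)
  # two dips 0.2 s apart, second deeper
  y <- -0.5 * exp(-((t - 0.4) / 0.03)^2) - 1.0 * exp(-((t - 0.6) / 0.03)^2)
  tr <- detect_troughs(y, t, trough_policy(min_separation = 0.4))
  expect_length(tr, 1)
  expect_lt(abs(t[tr] - 0.6), 0.02)
})

test_that("trough policy validates its fields", {
  expect_error(trough_policy(min_separation = 0),
               class = "gait_parameter_error")
  expect_error(trough_policy(prominence_fraction = 1.2),
               class = "gait_parameter_error")
})

test_that("noise-free detection hits every annotated event within one
          frame inside the walkway", {
  for (speed in c(0.8, 1.3)) {
    walk <- simulate_walk(walk_spec(speed = speed, seed = 17))
    res <- analyze_walk(walk$series, walk$camera, walk$depth, walk$walkway)
    expect_events_within(res, walk$truth$events,
                         walk$truth$t_cross_start,
                         walk$truth$t_cross_end, frames = 1)
  }
})

test_that("a standing subject produces no gait events", {
  walk <- simulate_walk(walk_spec(speed = 1.0, seed = 2))
  s <- walk$series
  keep <- s$t < 0.95  # before gait onset
  stand <- keypoint_series(
    as.data.frame(s[keep, c("t", "joint", "x", "y", "quality")]))
  nf <- n_frames(stand)
  d <- depth_track(frame_times(stand), walk$depth$z[seq_len(nf), ],
                   walk$depth$z0)
  sm <- smooth_series(to_world_view(to_camera_view(stand, walk$camera), d),
                      d)
  ev <- detect_events(sm, walk$walkway)
  expect_equal(nrow(ev), 0)
})

test_that("event detection needs the foot chain to be present", {
  walk <- simulate_walk(walk_spec(speed = 1.0, seed = 2))
  s <- walk$series
  kill <- s$joint %in% c("l_heel", "r_heel")
  s$quality[kill] <- 0; s$x[kill] <- NA; s$y[kill] <- NA
  d <- walk$depth
  sm <- smooth_series(to_world_view(to_camera_view(s, walk$camera), d), d)
  expect_error(detect_events(sm, walk$walkway),
               class = "gait_insufficient_data")
})

test_that("phases follow the stance/swing definitions", {
  ev <- data.frame(
    type = c("HEEL_STRIKE", "TOE_OFF", "HEEL_STRIKE"),
    side = "LEFT", frame = c(60, 96, 126), t = c(1.0, 1.6, 2.1),
    stringsAsFactors = FALSE)
  ph <- segment_phases(ev)
  expect_equal(nrow(ph), 2)
  expect_equal(ph$phase, c("STANCE", "SWING"))
  expect_equal(ph$start_t, c(1.0, 1.6))
  expect_equal(ph$end_t, c(1.6, 2.1))

  # single event: no phases
  expect_equal(nrow(segment_phases(ev[1, ])), 0)

  # consecutive same-type events warn and are skipped
  ev2 <- data.frame(
    type = c("HEEL_STRIKE", "HEEL_STRIKE", "TOE_OFF"),
    side = "RIGHT", frame = c(10, 70, 100), t = c(0.2, 1.2, 1.7),
    stringsAsFactors = FALSE)
  expect_warning(ph2 <- segment_phases(ev2),
                 class = "gait_sequencing_warning")
  expect_equal(nrow(ph2), 1)
  expect_equal(ph2$phase, "STANCE")
})

test_that("phases tile without overlap and recover the stance fraction", {
  walk <- simulate_walk(walk_spec(speed = 1.0, stance_fraction = 0.6,
                                  seed = 12))
  res <- analyze_walk(walk$series, walk$camera, walk$depth, walk$walkway)
  ph <- res$phases
  for (side in c("LEFT", "RIGHT")) {
    p <- ph[ph$side == side, ]
    p <- p[order(p$start_t), ]
    # consecutive phases share their boundary exactly (tiling, no overlap)
    expect_equal(p$start_t[-1], p$end_t[-nrow(p)])
    expect_true(all(p$phase[-1] != p$phase[-nrow(p)]))  # alternation
  }
  T_cycle <- 120 / walk$spec$cadence
  st <- ph[ph$phase == "STANCE", ]
  # drop initiation/termination stances; keep steady-state cycles
  st <- st[st$start_t >= walk$truth$t_cross_start &
             st$end_t <= walk$truth$t_cross_end, ]
  frac <- (st$end_t - st$start_t) / T_cycle
  expect_lt(max(abs(frac - 0.6)), 0.03)
})
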
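test_that("walk_spec ties speed, cadence and stride length together", {
  s <- walk_spec(speed = 1.0)
  expect_equal(s$speed, s$stride_length * s$cadence / 120, tolerance = 1e-9)
  s2 <- walk_spec(speed = 1.2, cadence = 110)
  expect_equal(s2$stride_length, 120 * 1.2 / 110, tolerance = 1e-9)
  expect_error(walk_spec(speed = 1.0, cadence = 100, stride_length = 1.0),
               class = "gait_specification_error")
  expect_error(walk_spec(speed = 3.0), class = "gait_specification_error")
  expect_error(walk_spec(stance_fraction = 0.4),
               class = "gait_specification_error")
})

test_that("simulation is bit-identical under a fixed seed and the truth
          is seed-independent", {
  s <- walk_spec(speed = 1.0, pixel_noise_sd = 2, dropout_prob = 0.01,
                 seed = 33)
  w1 <- simulate_walk(s)
  w2 <- simulate_walk(s)
  expect_identical(w1$series, w2$series)
  expect_identical(w1$truth, w2$truth)

  s2 <- walk_spec(speed = 1.0, pixel_noise_sd = 2, dropout_prob = 0.01,
                  seed = 34)
  w3 <- simulate_walk(s2)
  expect_false(identical(w1$series$x, w3$series$x))
  # kinematic ground truth does not depend on the noise seed
  expect_equal(w1$truth$events, w3$truth$events)
  expect_equal(w1$truth$speed, w3$truth$speed)
})

test_that("ground truth is internally consistent", {
  for (speed in c(0.6, 1.0, 1.6)) {
    walk <- simulate_walk(walk_spec(speed = speed, seed = 1))
    tr <- walk$truth
    expect_equal(tr$speed, tr$stride_length * tr$cadence / 120,
                 tolerance = 1e-9)
    T_cycle <- 120 / tr$cadence
    for (side in c("LEFT", "RIGHT")) {
      hs <- tr$events$t[tr$events$type == "HEEL_STRIKE" &
                          tr$events$side == side]
      if (length(hs) > 1) {
        expect_lt(max(abs(diff(hs) - T_cycle)), 1e-9)
      }
      # toe off follows heel strike by the stance fraction of a cycle
      to <- tr$events$t[tr$events$type == "TOE_OFF" &
                          tr$events$side == side]
      steady_hs <- hs[hs + tr$stance_fraction * T_cycle <= max(to) + 1e-9]
      for (h in steady_hs) {
        expect_lt(min(abs(to - (h + tr$stance_fraction * T_cycle))), 1e-9)
      }
    }
    expect_equal(tr$t_cross_end - tr$t_cross_start,
                 walk$spec$walkway_length / speed, tolerance = 1e-12)
  }
})

test_that("stance-phase feet have zero progression velocity in the
          noise-free world frame", {
  walk <- simulate_walk(walk_spec(speed = 1.2, seed = 3))
  wt <- to_world_view(to_camera_view(walk$series, walk$camera), walk$depth)
  prog <- gaitway:::.progression_matrix(wt, walk$walkway)
  t <- frame_times(wt)
  tr <- walk$truth
  for (side in c("LEFT", "RIGHT")) {
    hs <- tr$events$t[tr$events$type == "HEEL_STRIKE" &
                        tr$events$side == side]
    to <- tr$events$t[tr$events$type == "TOE_OFF" & tr$events$side == side]
    ankle <- prog[, gaitway:::.side_joint("ankle", side)]
    for (h in hs) {
      nxt <- to[to > h]
      if (length(nxt) == 0) next
      sel <- t >= h + 1e-6 & t <= nxt[1] - 1e-6
      if (sum(sel) > 1) {
        expect_lt(max(abs(diff(ankle[sel]))), 1e-9)
      }
    }
  }
})

test_that("the projected toe signal has one trough per gait cycle", {
  walk <- simulate_walk(walk_spec(speed = 1.0, seed = 6))
  wt <- to_world_view(to_camera_view(walk$series, walk$camera), walk$depth)
  sm <- smooth_series(wt, walk$depth)
  h <- gaitway:::.height_matrix(sm, walk$walkway)
  tr <- detect_troughs(h[, "r_big_toe"], frame_times(sm))
  n_toe_off <- sum(walk$truth$events$type == "TOE_OFF" &
                     walk$truth$events$side == "RIGHT")
  expect_equal(length(tr), n_toe_off)
})

test_that("pixel noise has the requested magnitude", {
  clean <- simulate_walk(walk_spec(speed = 1.0, seed = 44))
  noisy <- simulate_walk(walk_spec(speed = 1.0, pixel_noise_sd = 2,
                                   seed = 44))
  resid <- noisy$series$x - clean$series$x
  expect_lt(abs(stats::sd(resid) - 2), 0.2)  # within 10% of 2 px
})

test_that("quality dropout hits roughly its configured probability and
          drops coordinates", {
  walk <- simulate_walk(walk_spec(speed = 1.0, dropout_prob = 0.05,
                                  seed = 10))
  miss <- walk$series$quality == 0
  expect_gt(mean(miss), 0.03)
  expect_lt(mean(miss), 0.07)
  expect_true(all(is.na(walk$series$x[miss])))
})

test_that("cohorts are bounded, reproducible and warn when degenerate", {
  co <- simulate_cohort(10, c(0.6, 1.4), noise_sd = 0, dropout_prob = 0,
                        seed = 42)
  expect_length(co, 10)
  speeds <- vapply(co, function(w) w$truth$speed, numeric(1))
  expect_true(all(speeds >= 0.6 & speeds <= 1.4))
  co2 <- simulate_cohort(10, c(0.6, 1.4), noise_sd = 0, dropout_prob = 0,
                         seed = 42)
  expect_identical(speeds, vapply(co2, function(w) w$truth$speed,
                                  numeric(1)))
  expect_identical(co[[3]]$series, co2[[3]]$series)
  expect_warning(simulate_cohort(1, c(1, 1.2), seed = 1),
                 class = "gait_degenerate_input")
  expect_error(simulate_cohort(0, c(1, 1.2)),
               class = "gait_specification_error")
  expect_error(simulate_cohort(5, c(1.4, 0.6)),
               class = "gait_specification_error")
})

test_that("simulation does not disturb the global RNG stream", {
  set.seed(1)
  before <- runif(1)
  set.seed(1)
  invisible(simulate_walk(walk_spec(speed = 1.0, pixel_noise_sd = 2,
                                    seed = 99)))
  after <- runif(1)
  expect_identical(before, after)
})
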
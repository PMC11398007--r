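cam_demo <- camera_intrinsics(800, 800, 640, 360)

one_point_series <- function(x, y, t = 0) {
  xm <- matrix(x, length(t), 25)
  ym <- matrix(y, length(t), 25)
  qm <- matrix(1, length(t), 25)
  gaitway:::series_from_mats(t, xm, ym, qm)
}

test_that("camera view normalizes pixels by the intrinsics", {
  s <- one_point_series(640, 360)
  ct <- to_camera_view(s, cam_demo)
  expect_equal(unique(ct$xp), 0)
  expect_equal(unique(ct$yp), 0)

  s2 <- one_point_series(960, 360)
  ct2 <- to_camera_view(s2, cam_demo)
  expect_equal(unique(ct2$xp), 0.4)  # (960 - 640) / 800

  expect_error(camera_intrinsics(0, 800, 640, 360),
               class = "gait_parameter_error")
  expect_error(camera_intrinsics(800, -1, 640, 360),
               class = "gait_parameter_error")
})

test_that("camera view inverts back to pixels within 1e-9", {
  s <- make_series(20, seed = 11)
  ct <- to_camera_view(s, cam_demo)
  back <- camera_to_pixels(ct, cam_demo)
  expect_lt(max(abs(back$x - s$x)), 1e-9)
  expect_lt(max(abs(back$y - s$y)), 1e-9)
  expect_equal(back$t, s$t)
})

test_that("world view matches hand-evaluated values in both conventions", {
  t <- c(0, 1 / 60)
  s <- one_point_series(960, 360, t)
  ct <- to_camera_view(s, cam_demo)  # xp = 0.4 everywhere
  z0 <- 2
  d2 <- depth_track(t, rep(2 * z0, 2), z0 = z0)  # z = 2 z0
  wp <- to_world_view(ct, d2, "as_printed")
  expect_equal(unique(wp$X), 0.4 * 0.5)  # 0.2
  expect_equal(unique(wp$Z), 2)
  wh <- to_world_view(ct, d2, "pinhole")
  expect_equal(unique(wh$X), 0.4 * 2)  # 0.8
  expect_equal(unique(wh$Z), 2)
})

test_that("at reference depth the world view equals the camera view
          under both conventions", {
  s <- make_series(15, seed = 3)
  ct <- to_camera_view(s, cam_demo)
  d <- depth_track(frame_times(s), rep(3, 15), z0 = 3)
  for (conv in c("pinhole", "as_printed")) {
    w <- to_world_view(ct, d, conv)
    expect_equal(w$X, ct$xp, tolerance = 1e-12)
    expect_equal(w$Y, ct$yp, tolerance = 1e-12)
    expect_true(all(abs(w$Z - 1) < 1e-12))
  }
})

test_that("conventions differ by (z0/z)^2 on lateral coordinates", {
  t <- c(0, 1 / 60)
  s <- make_series(2, seed = 5)
  ct <- to_camera_view(s, cam_demo)
  # two-depth fixture: one frame at z0, one at 1.6 z0
  z0 <- 4
  d <- depth_track(t, c(z0, 1.6 * z0), z0 = z0)
  wp <- to_world_view(ct, d, "as_printed")
  wh <- to_world_view(ct, d, "pinhole")
  ratio <- (d$z / z0)[rep(1:2, each = 25)]
  expect_equal(wp$X * ratio^2, wh$X, tolerance = 1e-12)
  expect_equal(wp$Y * ratio^2, wh$Y, tolerance = 1e-12)
  expect_equal(wp$Z, wh$Z)
})

test_that("depth track validation and alignment errors fire", {
  expect_error(depth_track(0:1, c(1, -2), z0 = 1),
               class = "gait_parameter_error")
  expect_error(depth_track(0:1, c(1, 2), z0 = 0),
               class = "gait_parameter_error")
  s <- make_series(5)
  ct <- to_camera_view(s, cam_demo)
  d_short <- depth_track((0:2) / 60, rep(2, 3), z0 = 2)
  expect_error(to_world_view(ct, d_short), class = "gait_alignment_error")
})

test_that("walkway definition enforces its geometry", {
  expect_error(walkway_definition(c(0, 0, 1), c(0, 0, 1)),
               class = "gait_parameter_error")
  expect_error(walkway_definition(c(0, 0, 1), c(1, 0, 1), length = 4,
                                  scale = 3),
               class = "gait_parameter_error")
  expect_error(walkway_definition(c(0, 0, 1), c(1, 0, 1), length = 4,
                                  waypoint_spacing = 0.3),
               class = "gait_parameter_error")
  w <- walkway_definition(c(-0.5, 0.35, 1), c(0.5, 0.35, 1), length = 4)
  expect_equal(w$scale, 4)
})

test_that("progression is anchored, linear for a constant-speed walker,
          and sign-reverses with direction", {
  walk <- simulate_walk(walk_spec(speed = 1.0, seed = 2))
  ct <- to_camera_view(walk$series, walk$camera)
  wt <- to_world_view(ct, walk$depth)
  prog <- project_to_walkway_axis(wt, walk$walkway)
  t <- attr(prog, "t")
  moving <- t > walk$spec$onset_time + 0.1
  fit <- stats::lm(prog[moving] ~ t[moving])
  expect_equal(unname(stats::coef(fit)[2]), 1.0, tolerance = 1e-6)
  # subject stands start_offset before the start line
  expect_equal(prog[1], -walk$spec$start_offset, tolerance = 1e-9)

  # reversed walkway direction flips progression monotonicity
  rev_walkway <- walkway_definition(start = walk$walkway$end,
                                    end = walk$walkway$start,
                                    length = walk$walkway$length,
                                    scale = walk$walkway$scale)
  prog_rev <- project_to_walkway_axis(wt, rev_walkway)
  expect_true(all(diff(prog_rev[moving]) <= 1e-9))
})

test_that("progression is equivariant under rigid rotation of the world
          frame applied to track and walkway jointly", {
  walk <- simulate_walk(walk_spec(speed = 1.1, seed = 6))
  ct <- to_camera_view(walk$series, walk$camera)
  wt <- to_world_view(ct, walk$depth)
  prog <- project_to_walkway_axis(wt, walk$walkway)

  th <- 0.7  # rotation in the ground (X-Z) plane
  R <- function(p) c(cos(th) * p[1] + sin(th) * p[3], p[2],
                     -sin(th) * p[1] + cos(th) * p[3])
  wt2 <- wt
  X <- wt$X; Z <- wt$Z
  wt2$X <- cos(th) * X + sin(th) * Z
  wt2$Z <- -sin(th) * X + cos(th) * Z
  walkway2 <- walkway_definition(R(walk$walkway$start), R(walk$walkway$end),
                                 length = walk$walkway$length,
                                 scale = walk$walkway$scale)
  prog2 <- project_to_walkway_axis(wt2, walkway2)
  expect_equal(as.numeric(prog2), as.numeric(prog), tolerance = 1e-9)
})
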
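# shared fixtures and independent oracles, all built in code

# small synthetic screen-view series: smooth deterministic trajectories,
# not a gait pattern (for I/O and coordinate tests)
make_series <- function(n_frames = 10, fps = 60, seed = 1) {
  set.seed(seed)
  if (n_frames == 0) {
    z <- matrix(numeric(0), 0, 25)
    return(gaitway:::series_from_mats(numeric(0), z, z, z,
                                      nominal_fps = fps))
  }
  t <- (seq_len(n_frames) - 1) / fps
  base_x <- matrix(rep(runif(25, 100, 1800), each = n_frames), n_frames, 25)
  base_y <- matrix(rep(runif(25, 100, 1000), each = n_frames), n_frames, 25)
  x <- base_x + 40 * sin(2 * pi * t) + matrix(rnorm(n_frames * 25), n_frames)
  y <- base_y + 25 * cos(2 * pi * t) + matrix(rnorm(n_frames * 25), n_frames)
  q <- matrix(runif(n_frames * 25, 0.5, 1), n_frames, 25)
  gaitway:::series_from_mats(t, x, y, q, nominal_fps = fps)
}

# independent Savitzky-Golay oracle: explicit least-squares polynomial fit
# over one window, evaluated at the center via lm()
polyfit_center <- function(y, i, window, degree) {
  m <- (window - 1) / 2
  span <- (i - m):(i + m)
  keep <- span >= 1 & span <= length(y) & is.finite(y[span])
  xs <- (span - i)[keep]
  ys <- y[span][keep]
  d <- min(degree, length(ys) - 1)
  if (d == 0) return(mean(ys))
  fit <- stats::lm(ys ~ poly(xs, degree = d, raw = TRUE))
  unname(stats::predict(fit, newdata = data.frame(xs = 0)))
}

# greatest |detected - true| in frames, matching each true event to its
# nearest detection; Inf when a true event has no detection at all
match_events <- function(true_t, det_t, fps = 60) {
  if (length(true_t) == 0) return(0)
  if (length(det_t) == 0) return(Inf)
  max(vapply(true_t, function(x) min(abs(det_t - x)), numeric(1))) * fps
}

# independent permutation enumerator (recursive, list-based) for the
# Spearman exact-p oracle
perms_list <- function(v) {
  if (length(v) <= 1) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_list(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
  }
  out
}

# world track built directly from coordinate matrices (internal layout)
make_world_track <- function(t, X, Y, Z, quality = NULL, z0 = 4) {
  if (is.null(quality)) quality <- matrix(1, length(t), 25)
  out <- gaitway:::.track_df(t, X, Y, quality, c("X", "Y"), "world_track",
                             list(z0 = z0, convention = "pinhole",
                                  nominal_fps = 60))
  out$Z <- as.vector(t(Z))
  out
}

expect_events_within <- function(result, truth, t0, t1, frames = 1) {
  ev <- result$events
  for (ty in unique(truth$type)) {
    for (sd in c("LEFT", "RIGHT")) {
      tt <- truth$t[truth$type == ty & truth$side == sd &
                      truth$t >= t0 & truth$t <= t1]
      if (length(tt) == 0) next
      dd <- ev$t[ev$type == ty & ev$side == sd]
      expect_lte(match_events(tt, dd), frames + 1e-6,
                 label = sprintf("%s/%s timing error (frames)", ty, sd))
    }
  }
}
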
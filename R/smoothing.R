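#' Savitzky-Golay convolution weights
#'
#' Weights for the central point of a least-squares polynomial fit over a
#' symmetric window: smoothing a signal with these weights is equivalent to
#' fitting a degree-`degree` polynomial to each window of `window`
#' consecutive samples and evaluating it at the window center. The weights
#' always sum to 1 and reproduce polynomials up to `degree` exactly.
#'
#' @param window Odd window length (number of samples).
#' @param degree Polynomial degree, `0 <= degree < window`.
#' @return Numeric weight vector of length `window` (symmetric).
#' @export
#' @examples
#' savgol_coefficients(5, 2) * 35  # the classic (-3, 12, 17, 12, -3)
savgol_coefficients <- function(window, degree) {
  if (window %% 2 != 1 || window < 1) {
    stop(gait_error("gait_parameter_error", "window must be odd and >= 1"))
  }
  if (degree < 0 || degree >= window) {
    stop(gait_error("gait_parameter_error",
                    "degree must satisfy 0 <= degree < window"))
  }
  m <- (window - 1L) / 2L
  A <- outer(seq(-m, m), 0:degree, `^`)
  # central-point evaluation row of the least-squares hat matrix
  w <- solve(crossprod(A), t(A))[1L, ]
  as.numeric(w)
}

#' Distance-adaptive smoothing policy
#'
#' The smoothing filter widens its window for subjects farther from the
#' camera: pixel amplitudes shrink with distance so the relative noise
#' level grows, and a wider local polynomial fit compensates. The realized
#' window at frame `i` is the nearest odd value of
#' `base_window * distance_scaling(z_i / z0)`, clamped to
#' `[min_window, max_window]`; the polynomial degree is fixed by
#' `degree` (reduced automatically where a shrunken edge window would not
#' support it).
#'
#' @param base_window Odd window length at the reference depth (default 9,
#'   i.e. 150 ms at 60 fps).
#' @param min_window,max_window Odd clamp bounds (defaults 5 and 21).
#' @param degree Polynomial degree (default 3, standard for kinematic
#'   traces).
#' @param distance_scaling Function mapping the depth ratio `z/z0` to a
#'   window multiplier; default identity (linear growth with distance).
#' @return A `smoothing_policy` object.
#' @export
smoothing_policy <- function(base_window = 9, min_window = 5,
                             max_window = 21, degree = 3,
                             distance_scaling = identity) {
  for (w in c(base_window, min_window, max_window)) {
    if (w %% 2 != 1 || w < 1) {
      stop(gait_error("gait_parameter_error", "windows must be odd and >= 1"))
    }
  }
  if (!(min_window <= base_window && base_window <= max_window)) {
    stop(gait_error("gait_parameter_error",
                    "need min_window <= base_window <= max_window"))
  }
  if (degree < 0 || degree >= min_window) {
    stop(gait_error("gait_parameter_error",
                    "degree must satisfy 0 <= degree < min_window"))
  }
  structure(list(base_window = base_window, min_window = min_window,
                 max_window = max_window, degree = degree,
                 distance_scaling = distance_scaling),
            class = "smoothing_policy")
}

# realized odd windows per frame from depth ratios
.policy_windows <- function(policy, ratio) {
  m <- policy$base_window * policy$distance_scaling(ratio)
  w <- 2 * round((m - 1) / 2) + 1
  pmin(pmax(w, policy$min_window), policy$max_window)
}

# Smooth one signal with per-frame windows. Interior frames sharing a
# window are handled with a single convolution; edge frames (window
# shrinkage) and frames whose stencil covers an NA fall back to a direct
# least-squares fit on the available samples.
.smooth_signal <- function(y, windows, degree) {
  n <- length(y)
  if (n == 0) return(y)
  idx <- seq_len(n)
  half <- (windows - 1) / 2
  edge_half <- pmin(half, idx - 1L, n - idx)
  w_eff <- 2 * edge_half + 1
  d_eff <- pmin(degree, w_eff - 1)

  na_pos <- which(!is.finite(y))
  touches_na <- rep(FALSE, n)
  if (length(na_pos) > 0) {
    for (p in na_pos) {
      lo <- max(1L, p - max(half)); hi <- min(n, p + max(half))
      span <- lo:hi
      touches_na[span] <- touches_na[span] |
        (abs(span - p) <= half[span])
    }
  }

  out <- rep(NA_real_, n)
  direct <- touches_na | w_eff < windows
  for (w in unique(w_eff[!direct])) {
    sel <- !direct & w_eff == w
    co <- savgol_coefficients(w, min(degree, w - 1))
    conv <- stats::filter(y, co, method = "convolution", sides = 2)
    out[sel] <- conv[sel]
  }
  for (i in which(direct)) {
    h <- edge_half[i]
    span <- (i - h):(i + h)
    yy <- y[span]
    keep <- is.finite(yy)
    d <- min(d_eff[i], sum(keep) - 1)
    if (sum(keep) == 0 || d < 0) next
    xs <- (span - i)[keep]
    A <- outer(xs, 0:d, `^`)
    fit <- tryCatch(qr.coef(qr(A), yy[keep])[1], error = function(e) NA_real_)
    out[i] <- fit
  }
  out
}

.smooth_track_fields <- function(obj, fields, ratio, policy) {
  windows <- .policy_windows(policy, ratio)
  t <- frame_times(obj)
  for (f in fields) {
    m <- kp_mat(obj, f)
    for (j in seq_len(ncol(m))) {
      m[, j] <- .smooth_signal(m[, j], windows, policy$degree)
    }
    obj[[f]] <- as.vector(t(m))
  }
  attr(obj, "smoothing_windows") <- windows
  attr(obj, "smoothing_degree") <- policy$degree
  obj
}

#' Smooth a keypoint series or track
#'
#' Applies the distance-adaptive Savitzky-Golay filter to every joint
#' signal: each value is replaced by the weighted sum of its window
#' neighborhood, with the window chosen per frame from the subject's depth
#' via the [smoothing_policy()]. Near the boundaries the window shrinks
#' symmetrically to the largest valid odd width rather than padding, so no
#' data is fabricated at walk onset/offset where timing is measured.
#' Missing samples (quality 0 / non-finite) are excluded from the local
#' fits.
#'
#' @param x A `world_track`, `camera_track` or `keypoint_series`.
#' @param depth A [depth_track()] supplying per-frame depth. Optional for
#'   `world_track` inputs, whose `Z` column already carries `z/z0`.
#' @param policy A [smoothing_policy()].
#' @return An object of the same class with smoothed coordinate columns;
#'   the realized per-frame windows are attached as attribute
#'   `"smoothing_windows"` for audit.
#' @export
smooth_series <- function(x, depth = NULL, policy = smoothing_policy()) {
  UseMethod("smooth_series")
}

.depth_ratio <- function(depth, nf) {
  if (is.null(depth)) {
    return(rep(1, nf))
  }
  apply(depth$z / depth$z0, 1, stats::median)
}

.check_length <- function(nf, policy) {
  if (nf < policy$min_window) {
    stop(gait_error("gait_length_error",
                    sprintf("series has %d frames; need at least %d",
                            nf, policy$min_window)))
  }
}

#' @rdname smooth_series
#' @export
smooth_series.world_track <- function(x, depth = NULL,
                                      policy = smoothing_policy()) {
  nf <- n_frames(x)
  .check_length(nf, policy)
  ratio <- if (is.null(depth)) {
    apply(kp_mat(x, "Z"), 1, stats::median)
  } else {
    .depth_ratio(depth, nf)
  }
  .smooth_track_fields(x, c("X", "Y", "Z"), ratio, policy)
}

#' @rdname smooth_series
#' @export
smooth_series.camera_track <- function(x, depth = NULL,
                                       policy = smoothing_policy()) {
  nf <- n_frames(x)
  .check_length(nf, policy)
  .smooth_track_fields(x, c("xp", "yp"), .depth_ratio(depth, nf), policy)
}

#' @rdname smooth_series
#' @export
smooth_series.keypoint_series <- function(x, depth = NULL,
                                          policy = smoothing_policy()) {
  nf <- n_frames(x)
  .check_length(nf, policy)
  .smooth_track_fields(x, c("x", "y"), .depth_ratio(depth, nf), policy)
}
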
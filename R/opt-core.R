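# Parallel-beam OPT simulation and filtered back-projection reconstruction.
#
# Geometry: each slice (axis 1 of the voxel grid) is processed independently.
# Pixel (x, y) in centred slice coordinates contributes to detector position
# s = x*cos(theta) + y*sin(theta); the forward projection integrates along
# the orthogonal direction t. Angles cover [0, 360) endpoint-exclusive, so
# opposing views are acquired redundantly, as in a full-rotation acquisition.

# Per-angle resampling weights for a square slice: bilinear gather of the
# rotated (s, t) grid. Returns indices/weights into a column-major slice.
radon_weights <- function(n, theta) {
  c0 <- (n + 1) / 2
  sc <- seq_len(n) - c0
  tc <- sc
  # t varies fastest within each detector bin s
  t_g <- rep(tc, times = n)
  s_g <- rep(sc, each = n)
  x <- c0 + s_g * cos(theta) - t_g * sin(theta)
  y <- c0 + s_g * sin(theta) + t_g * cos(theta)
  r0 <- floor(y); cc0 <- floor(x)
  fr <- y - r0; fc <- x - cc0
  idx <- function(rr, cc) {
    ok <- rr >= 1 & rr <= n & cc >= 1 & cc <= n
    list(i = ifelse(ok, (cc - 1) * n + rr, 1L), ok = ok)
  }
  p1 <- idx(r0, cc0); p2 <- idx(r0 + 1, cc0)
  p3 <- idx(r0, cc0 + 1); p4 <- idx(r0 + 1, cc0 + 1)
  list(
    i1 = p1$i, w1 = (1 - fr) * (1 - fc) * p1$ok,
    i2 = p2$i, w2 = fr * (1 - fc) * p2$ok,
    i3 = p3$i, w3 = (1 - fr) * fc * p3$ok,
    i4 = p4$i, w4 = fr * fc * p4$ok
  )
}

#' Simulate a parallel-beam OPT acquisition
#'
#' Computes, for each slice along the sample long axis, line integrals of the
#' intensity at `n_angles` rotation angles `k * 360 / n_angles` (k = 0, ...,
#' n_angles - 1). The detector width equals the (square) slice width and the
#' rotation axis sits at the detector-column centre.
#'
#' @param volume A `voxel_grid` with a square cross-section.
#' @param n_angles Number of projection angles over 360 degrees (>= 2);
#'   typical acquisitions use 400 or 1200.
#' @return A [projection_set()].
#' @export
forward_project <- function(volume, n_angles) {
  stopifnot(inherits(volume, "voxel_grid"))
  if (!is.numeric(n_angles) || n_angles < 2) {
    stop_parameter("`n_angles` must be at least 2.")
  }
  n_angles <- as.integer(n_angles)
  d <- dim(volume$data)
  if (d[2] != d[3]) {
    stop_parameter("forward projection requires a square slice cross-section.")
  }
  if (any(!is.finite(volume$data))) {
    stop_parameter("volume contains non-finite voxels.")
  }
  n <- d[2]
  nz <- d[1]
  angles <- (seq_len(n_angles) - 1) * 360 / n_angles

  # slices as columns, column-major (row index fastest)
  V <- matrix(aperm(volume$data, c(2, 3, 1)), n * n, nz)
  proj <- array(0, c(n_angles, nz, n))
  for (a in seq_len(n_angles)) {
    w <- radon_weights(n, angles[a] * pi / 180)
    samp <- w$w1 * V[w$i1, , drop = FALSE] + w$w2 * V[w$i2, , drop = FALSE] +
      w$w3 * V[w$i3, , drop = FALSE] + w$w4 * V[w$i4, , drop = FALSE]
    dim(samp) <- c(n, n, nz) # (t, s, slice)
    prof <- colSums(samp) # (s, slice)
    proj[a, , ] <- t(prof)
  }
  projection_set(proj, angles, volume$voxel_size, volume$channel)
}

ramp_multiplier <- function(p, window) {
  f <- c(seq(0, p / 2), seq(-p / 2 + 1, -1)) / p
  ramp <- 2 * abs(f)
  if (window == "hann") {
    ramp <- ramp * (0.5 + 0.5 * cos(2 * pi * f))
  }
  ramp
}

#' Ramp-filter a projection profile
#'
#' Frequency-domain multiplication by the ramp `2|f|` (optionally apodised by
#' a Hann window), with zero-padding to the next power of two (at least twice
#' the profile length) to suppress wrap-around. With the Ram-Lak window the
#' DC component of the output is exactly zero.
#'
#' @param profile Numeric vector (length >= 2) or matrix whose columns are
#'   profiles.
#' @param window `"ramlak"` (default) or `"hann"`.
#' @return Filtered profile(s), same shape as the input.
#' @export
ramp_filter <- function(profile, window = c("ramlak", "hann")) {
  window <- match.arg(window)
  vec <- is.null(dim(profile))
  m <- if (vec) matrix(profile, ncol = 1) else profile
  n <- nrow(m)
  if (n < 2) stop_parameter("profile length must be at least 2.")
  p <- next_pow2(2L * n)
  pad <- rbind(m, matrix(0, p - n, ncol(m)))
  ramp <- ramp_multiplier(p, window)
  out <- Re(mvfft(mvfft(pad) * ramp, inverse = TRUE)) / p
  out <- out[seq_len(n), , drop = FALSE]
  if (vec) drop(out) else out
}

#' Filtered back-projection reconstruction
#'
#' Slice-by-slice FBP: each detector row is ramp-filtered, then smeared back
#' across the slice with bilinear interpolation, and the sum is scaled by
#' `pi / (2 * n_angles)`. Values outside the inscribed reconstruction circle
#' are set to zero (outside the measured region).
#'
#' @param ps A [projection_set()] with at least 2 angles.
#' @param window Ramp apodisation, `"ramlak"` (default) or `"hann"`.
#' @return A `voxel_grid` of shape `(rows, width, width)` where `width` is the
#'   detector width.
#' @export
reconstruct_fbp <- function(ps, window = c("ramlak", "hann")) {
  stopifnot(inherits(ps, "projection_set"))
  window <- match.arg(window)
  d <- dim(ps$projections)
  n_angles <- d[1]; nz <- d[2]; n <- d[3]
  if (n_angles < 2) stop_parameter("need at least 2 projection angles.")

  c0 <- (n + 1) / 2
  xc <- rep(seq_len(n) - c0, each = n) # column-major: row (y) fastest
  yc <- rep(seq_len(n) - c0, times = n)
  p <- next_pow2(2L * n)
  ramp <- ramp_multiplier(p, window)

  accum <- matrix(0, n * n, nz)
  for (a in seq_len(n_angles)) {
    th <- ps$angles_deg[a] * pi / 180
    sino <- t(matrix(ps$projections[a, , ], nz, n)) # (s, slice)
    pad <- rbind(sino, matrix(0, p - n, nz))
    q <- Re(mvfft(mvfft(pad) * ramp, inverse = TRUE))[seq_len(n), , drop = FALSE] / p
    s <- xc * cos(th) + yc * sin(th) + c0
    i0 <- floor(s)
    fr <- s - i0
    ok0 <- i0 >= 1 & i0 <= n
    ok1 <- i0 + 1 >= 1 & i0 + 1 <= n
    j0 <- ifelse(ok0, i0, 1L)
    j1 <- ifelse(ok1, i0 + 1L, 1L)
    accum <- accum +
      ((1 - fr) * ok0) * q[j0, , drop = FALSE] +
      (fr * ok1) * q[j1, , drop = FALSE]
  }
  accum <- accum * pi / (2 * n_angles)
  inside <- sqrt(xc^2 + yc^2) <= (n - 1) / 2
  accum[!inside, ] <- 0
  vol <- aperm(array(accum, c(n, n, nz)), c(3, 1, 2))
  voxel_grid(vol, ps$detector_pixel_size, ps$channel)
}

#' Mask of the inscribed reconstruction circle
#'
#' @param n Slice width in pixels.
#' @return Logical `n x n` matrix, `TRUE` inside the inscribed circle.
#' @export
reconstruction_circle <- function(n) {
  c0 <- (n + 1) / 2
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  matrix(sqrt((g$y - c0)^2 + (g$x - c0)^2) <= (n - 1) / 2, n, n)
}
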
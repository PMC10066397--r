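# Virtual unfolding of the tubular gut wall.
#
# Per slice: segment the tissue from lumen and background, take the outer
# outline, pick a seam at a fixed angle from the centroid, re-parameterise
# the outline by arc length starting at the seam, and sample intensities
# along inward surface normals. Stacking the straightened slices and
# reslicing orthogonally yields the unfolded volume, whose layers run from
# the outermost wall to the lumen.

#' Segment the tissue cross-section of one slice
#'
#' Automatic global (Otsu) threshold, hole filling, retention of the largest
#' connected component; the outline is the outer boundary polyline and the
#' centroid is the first-moment centroid of the filled mask.
#'
#' @param slice_img Numeric matrix (rows = y, cols = x).
#' @param slice_index Optional slice index stored in the result.
#' @return A `tissue_outline`: list with `polygon` (tibble `x`, `y`, ordered
#'   closed polyline, 1-based pixel coordinates), `centroid` (named vector
#'   `x`, `y`), `area_px`, `mask`, `slice_index` and `seam_vertex` (`NA` until
#'   [compute_seam()] is applied).
#' @export
segment_tissue <- function(slice_img, slice_index = NA_integer_) {
  if (!is.matrix(slice_img)) stop_parameter("`slice_img` must be a matrix.")
  rng <- range(slice_img)
  if (!all(is.finite(rng)) || diff(rng) <= 0) {
    abort("no foreground: slice has no intensity contrast.",
      class = "gutopt_empty_mask_error"
    )
  }
  norm <- (slice_img - rng[1]) / diff(rng)
  th <- EBImage::otsu(norm)
  mask <- norm > th
  if (!any(mask)) {
    abort("no foreground survives thresholding.", class = "gutopt_empty_mask_error")
  }
  mask <- EBImage::fillHull(mask)
  lab <- EBImage::bwlabel(mask)
  sizes <- tabulate(lab[lab > 0])
  biggest <- which.max(sizes)
  mask <- lab == biggest

  oc <- EBImage::ocontour(EBImage::bwlabel(mask))[[1]]
  # ocontour is 0-based in (first dim, second dim) = (row, col) = (y, x)
  poly <- tibble(x = oc[, 2] + 1, y = oc[, 1] + 1)
  idx <- which(mask, arr.ind = TRUE)
  centroid <- c(x = mean(idx[, 2]), y = mean(idx[, 1]))

  structure(
    list(
      slice_index = slice_index,
      polygon = poly,
      centroid = centroid,
      area_px = sum(mask),
      mask = mask,
      seam_vertex = NA_integer_
    ),
    class = "tissue_outline"
  )
}

#' @export
print.tissue_outline <- function(x, ...) {
  cat(sprintf(
    "<tissue_outline> slice %s: %d vertices, area %d px, centroid (%.1f, %.1f)%s\n",
    ifelse(is.na(x$slice_index), "?", x$slice_index),
    nrow(x$polygon), x$area_px, x$centroid[["x"]], x$centroid[["y"]],
    if (is.na(x$seam_vertex)) "" else sprintf(", seam vertex %d", x$seam_vertex)
  ))
  invisible(x)
}

# Angular position of points relative to a centre, counterclockwise from the
# +x image axis with y pointing down, in [0, 2*pi).
image_angle <- function(x, y, centre) {
  atan2(centre[["y"]] - y, x - centre[["x"]]) %% (2 * pi)
}

#' Select the unfolding seam on a tissue outline
#'
#' The seam is the polygon vertex closest in angle to the ray cast from the
#' centroid at `angle_deg`, measured counterclockwise from the +x image axis
#' in the y-down image convention. Ties break to the lowest vertex index.
#'
#' @param outline A `tissue_outline` from [segment_tissue()].
#' @param angle_deg Seam angle in degrees (default 45); any real value is
#'   reduced modulo 360.
#' @return The outline with `seam_vertex` set.
#' @export
compute_seam <- function(outline, angle_deg = 45) {
  stopifnot(inherits(outline, "tissue_outline"))
  a <- (angle_deg %% 360) * pi / 180
  ang <- image_angle(outline$polygon$x, outline$polygon$y, outline$centroid)
  d <- abs((ang - a + pi) %% (2 * pi) - pi)
  outline$seam_vertex <- which.min(d) # which.min takes the first (lowest index)
  outline
}

# Closed-polygon moving average smoothing (window must be odd).
smooth_polygon <- function(poly, window = 5L) {
  n <- nrow(poly)
  if (n <= window) {
    return(poly)
  }
  h <- (window - 1L) %/% 2L
  wrap <- function(i) ((i - 1L) %% n) + 1L
  sx <- numeric(n)
  sy <- numeric(n)
  for (o in -h:h) {
    j <- wrap(seq_len(n) + o)
    sx <- sx + poly$x[j]
    sy <- sy + poly$y[j]
  }
  tibble(x = sx / window, y = sy / window)
}

# Orient a closed polygon counterclockwise in the y-down image convention
# (i.e. the image_angle of its vertices increases along the traversal).
# Shoelace area computed in raw (x, y) coordinates is positive for a
# clockwise visual traversal when y points down, so we require it negative.
orient_ccw <- function(poly) {
  x <- poly$x
  y <- poly$y
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  a <- sum(x * y2 - x2 * y) / 2
  if (a > 0) poly[rev(seq_len(nrow(poly))), ] else poly
}

# Resample a closed polyline at arc-length spacing `step` (same units as the
# coordinates), starting at vertex `start`. Returns points and the perimeter.
resample_closed <- function(poly, start, step) {
  n <- nrow(poly)
  ord <- c(start:n, seq_len(start - 1L))
  x <- poly$x[ord]
  y <- poly$y[ord]
  dx <- diff(c(x, x[1]))
  dy <- diff(c(y, y[1]))
  seg <- sqrt(dx^2 + dy^2)
  cum <- c(0, cumsum(seg))
  per <- cum[n + 1]
  m <- max(4L, round(per / step))
  s <- (seq_len(m) - 1) * per / m # uniform, exactly closing the loop
  xi <- approx(cum, c(x, x[1]), xout = s)$y
  yi <- approx(cum, c(y, y[1]), xout = s)$y
  list(x = xi, y = yi, perimeter = per, n = m)
}

#' Straighten one slice along its tissue outline
#'
#' Re-parameterises the (smoothed) outline by arc length starting at the seam
#' and traversing counterclockwise, then samples the slice by bilinear
#' interpolation along the inward surface normal at each arc-length position,
#' from `band_outer` outside the outline to `band_inner` inside it.
#'
#' @param slice_img Numeric matrix (rows = y, cols = x).
#' @param outline A `tissue_outline` with the seam set (see [compute_seam()]).
#' @param band_inner Sampling depth inward of the outline, micrometres.
#' @param band_outer Sampling depth outward of the outline, micrometres.
#' @param step Arc-length sampling step in micrometres (defaults to one
#'   pixel).
#' @param pixel_size Pixel size in micrometres.
#' @param smooth_window Moving-average window (vertices) applied to the
#'   outline before re-parameterisation, suppressing pixelation jitter.
#' @return Numeric matrix: rows = radial depth (outermost first, lumen side
#'   last), columns = arc length from the seam. Attributes `perimeter_um`,
#'   `depth_um` (per-row depth relative to the outline, negative = outside)
#'   and `seam_xy`.
#' @export
straighten_slice <- function(slice_img, outline, band_inner, band_outer,
                             step = pixel_size, pixel_size = 1,
                             smooth_window = 5L) {
  stopifnot(inherits(outline, "tissue_outline"))
  if (is.na(outline$seam_vertex)) {
    stop_parameter("outline has no seam; call compute_seam() first.")
  }
  if (band_inner < 0 || band_outer < 0) {
    stop_parameter("bands must be non-negative.")
  }
  poly <- smooth_polygon(outline$polygon, smooth_window)
  seam_xy <- c(
    x = outline$polygon$x[outline$seam_vertex],
    y = outline$polygon$y[outline$seam_vertex]
  )
  poly <- orient_ccw(poly)
  start <- which.min((poly$x - seam_xy[["x"]])^2 + (poly$y - seam_xy[["y"]])^2)
  rs <- resample_closed(poly, start, step / pixel_size)

  # tangents by central difference on the closed resampled curve
  m <- rs$n
  nxt <- c(2:m, 1L)
  prv <- c(m, 1:(m - 1L))
  tx <- rs$x[nxt] - rs$x[prv]
  ty <- rs$y[nxt] - rs$y[prv]
  tl <- sqrt(tx^2 + ty^2)
  tx <- tx / tl
  ty <- ty / tl
  # inward normal: rotate the tangent, pick the sign pointing at the centroid
  nx <- -ty
  nyv <- tx
  flip <- nx * (outline$centroid[["x"]] - rs$x) +
    nyv * (outline$centroid[["y"]] - rs$y) < 0
  nx[flip] <- -nx[flip]
  nyv[flip] <- -nyv[flip]

  # clamp inward depth where the normal would cross the centroid
  dist_c <- sqrt((outline$centroid[["x"]] - rs$x)^2 +
    (outline$centroid[["y"]] - rs$y)^2) * pixel_size
  if (band_inner > min(dist_c)) {
    warn("band_inner exceeds the distance to the centroid for some columns; clamping.",
      class = "gutopt_geometry_warning"
    )
  }
  depth_um <- seq(-band_outer, band_inner, by = pixel_size)
  out <- matrix(0, length(depth_um), m)
  for (i in seq_along(depth_um)) {
    d_eff <- pmin(depth_um[i], 0.98 * dist_c) / pixel_size
    px <- rs$x + nx * d_eff
    py <- rs$y + nyv * d_eff
    out[i, ] <- bilinear_sample(slice_img, py, px)
  }
  attr(out, "perimeter_um") <- rs$perimeter * pixel_size
  attr(out, "depth_um") <- depth_um
  attr(out, "seam_xy") <- seam_xy
  out
}

#' Virtually unfold a tubular volume
#'
#' Applies per-slice segmentation, seam selection and straightening to every
#' slice of the volume, pads the straightened images to the maximum arc
#' length (zero fill, seam aligned at column 1), and reslices the straightened
#' stack orthogonally so that each layer of the unfolded volume is one radial
#' depth, spanning the outermost wall layers down to the lumen.
#'
#' @param volume A `voxel_grid`.
#' @param angle_deg Seam angle in degrees (default 45).
#' @param band_inner,band_outer Sampling depths inward/outward of the outline
#'   in micrometres.
#' @param step Arc-length step in micrometres (defaults to one voxel).
#' @param smooth_window Outline smoothing window (vertices).
#' @return An `unfold_result`: list with `straightened_stack` (array
#'   `slice x depth x arc`), `unfolded_volume` (array `depth x slice x arc`,
#'   an axis transposition of the former), `seams` (per-slice tibble),
#'   `depth_um`, `band_inner`, `band_outer`, `step`, `voxel_size`.
#' @export
unfold_volume <- function(volume, angle_deg = 45, band_inner, band_outer,
                          step = volume$voxel_size, smooth_window = 5L) {
  stopifnot(inherits(volume, "voxel_grid"))
  d <- dim(volume$data)
  nz <- d[1]
  vox <- volume$voxel_size

  res <- vector("list", nz)
  seams <- vector("list", nz)
  failed <- logical(nz)
  for (k in seq_len(nz)) {
    r <- tryCatch(
      {
        ol <- segment_tissue(volume$data[k, , ], slice_index = k)
        ol <- compute_seam(ol, angle_deg)
        mat <- straighten_slice(volume$data[k, , ], ol,
          band_inner = band_inner, band_outer = band_outer,
          step = step, pixel_size = vox, smooth_window = smooth_window
        )
        list(mat = mat, outline = ol)
      },
      gutopt_empty_mask_error = function(e) e
    )
    if (inherits(r, "error")) {
      failed[k] <- TRUE
      seams[[k]] <- tibble(
        slice = k, centroid_x = NA_real_, centroid_y = NA_real_,
        seam_x = NA_real_, seam_y = NA_real_, perimeter_um = NA_real_,
        ok = FALSE
      )
    } else {
      res[[k]] <- r$mat
      sx <- attr(r$mat, "seam_xy")
      seams[[k]] <- tibble(
        slice = k,
        centroid_x = r$outline$centroid[["x"]],
        centroid_y = r$outline$centroid[["y"]],
        seam_x = sx[["x"]], seam_y = sx[["y"]],
        perimeter_um = attr(r$mat, "perimeter_um"),
        ok = TRUE
      )
    }
  }
  if (all(failed)) {
    abort("no slice could be segmented.", class = "gutopt_empty_mask_error")
  }
  if (mean(failed) > 0.2) {
    abort(
      sprintf(
        "unfolding aborted: %d of %d slices failed segmentation (first failures: %s).",
        sum(failed), nz, paste(head(which(failed), 5), collapse = ", ")
      ),
      class = "gutopt_empty_mask_error"
    )
  }

  n_depth <- length(attr(res[[which(!failed)[1]]], "depth_um"))
  n_arc <- max(map_int(res[!failed], ncol))
  stack <- array(0, c(nz, n_depth, n_arc))
  for (k in seq_len(nz)) {
    if (failed[k]) next
    r <- res[[k]]
    stack[k, , seq_len(ncol(r))] <- r
  }

  structure(
    list(
      straightened_stack = stack,
      unfolded_volume = aperm(stack, c(2, 1, 3)),
      seams = bind_rows(seams),
      depth_um = attr(res[[which(!failed)[1]]], "depth_um"),
      band_inner = band_inner,
      band_outer = band_outer,
      step = step,
      voxel_size = vox
    ),
    class = "unfold_result"
  )
}

#' @export
print.unfold_result <- function(x, ...) {
  d <- dim(x$straightened_stack)
  cat(sprintf(
    "<unfold_result> %d slices x %d depths x %d arc samples (step %.3g um, band -%g..+%g um)\n",
    d[1], d[2], d[3], x$step, x$band_outer, x$band_inner
  ))
  cat(sprintf("  %d/%d slices segmented\n", sum(x$seams$ok), nrow(x$seams)))
  invisible(x)
}

#' Extract one radial layer of an unfolded volume
#'
#' @param x An `unfold_result`.
#' @param depth_um Radial depth (um) relative to the outline; positive values
#'   lie inward (toward the lumen). The nearest sampled layer is returned.
#' @return Matrix `slice x arc`.
#' @export
unfolded_layer <- function(x, depth_um) {
  stopifnot(inherits(x, "unfold_result"))
  i <- which.min(abs(x$depth_um - depth_um))
  x$unfolded_volume[i, , ]
}

#' @export
tidy.unfold_result <- function(x, ...) {
  x$seams
}
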
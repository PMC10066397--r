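# Core data containers: single-channel voxel grids, projection sets and
# two-channel overlays.

#' Create a voxel grid
#'
#' A `voxel_grid` is a 3D single-channel intensity array with an isotropic
#' voxel size in micrometres. Axis 1 is the sample long axis (one slice per
#' index), axis 2 is the image row (y, pointing down) and axis 3 the image
#' column (x).
#'
#' @param data Numeric 3D array, dimensions `(slices, rows, cols)`. A matrix
#'   is promoted to a single-slice volume.
#' @param voxel_size Isotropic voxel edge length in micrometres.
#' @param channel Optional channel label.
#' @return An object of class `voxel_grid`.
#' @export
voxel_grid <- function(data, voxel_size, channel = "unlabelled") {
  if (is.matrix(data)) {
    data <- array(data, c(1L, dim(data)))
  }
  if (length(dim(data)) != 3L) {
    stop_parameter("`data` must be a 3D array (slices x rows x cols).")
  }
  if (!is.numeric(voxel_size) || length(voxel_size) != 1L || voxel_size <= 0) {
    stop_parameter("`voxel_size` must be a single positive number (micrometres).")
  }
  if (any(!is.finite(data))) {
    stop_parameter("voxel grid contains non-finite intensities.")
  }
  structure(
    list(data = data, voxel_size = voxel_size, channel = as.character(channel)),
    class = "voxel_grid"
  )
}

#' @export
dim.voxel_grid <- function(x) dim(x$data)

#' @export
print.voxel_grid <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<voxel_grid> %d x %d x %d voxels, %.3g um/voxel, channel '%s'\n",
    d[1], d[2], d[3], x$voxel_size, x$channel
  ))
  cat(sprintf(
    "  extent: %.0f x %.0f x %.0f um, intensity range [%.3g, %.3g]\n",
    d[1] * x$voxel_size, d[2] * x$voxel_size, d[3] * x$voxel_size,
    min(x$data), max(x$data)
  ))
  invisible(x)
}

#' Create a projection set
#'
#' An ordered stack of 2D parallel-beam projections together with their
#' rotation angles. Dimension 1 indexes the angle, dimension 2 the detector
#' row (one per sample slice) and dimension 3 the detector column.
#'
#' @param projections Numeric 3D array `(angles, detector rows, detector cols)`.
#' @param angles_deg Strictly increasing rotation angles in `[0, 360)`.
#' @param detector_pixel_size Detector pixel pitch in micrometres.
#' @param channel Optional channel label.
#' @return An object of class `projection_set`.
#' @export
projection_set <- function(projections, angles_deg, detector_pixel_size,
                           channel = "unlabelled") {
  if (length(dim(projections)) != 3L) {
    stop_parameter("`projections` must be a 3D array (angle x row x col).")
  }
  if (dim(projections)[1] != length(angles_deg)) {
    stop_parameter("number of projections does not match number of angles.")
  }
  if (any(diff(angles_deg) <= 0) || any(angles_deg < 0) || any(angles_deg >= 360)) {
    stop_parameter("`angles_deg` must be strictly increasing within [0, 360).")
  }
  structure(
    list(
      projections = projections, angles_deg = angles_deg,
      detector_pixel_size = detector_pixel_size, channel = as.character(channel)
    ),
    class = "projection_set"
  )
}

#' @export
print.projection_set <- function(x, ...) {
  d <- dim(x$projections)
  cat(sprintf(
    "<projection_set> %d angles x %d rows x %d detector bins (step %.3g deg, channel '%s')\n",
    d[1], d[2], d[3], if (d[1] > 1) x$angles_deg[2] - x$angles_deg[1] else NA_real_,
    x$channel
  ))
  invisible(x)
}

#' Overlay two reconstructed channels
#'
#' Stacks two voxel grids of identical geometry into a lossless two-channel
#' volume, preserving channel labels and argument order.
#'
#' @param a,b `voxel_grid` objects with equal shapes and voxel sizes.
#' @return A `multi_channel_volume`: list with elements `channels` (named list
#'   of `voxel_grid`s in argument order) and `voxel_size`.
#' @export
overlay_channels <- function(a, b) {
  stopifnot(inherits(a, "voxel_grid"), inherits(b, "voxel_grid"))
  if (!identical(dim(a$data), dim(b$data))) {
    stop_geometry("cannot overlay channels: voxel grid shapes differ.")
  }
  if (!isTRUE(all.equal(a$voxel_size, b$voxel_size))) {
    stop_geometry("cannot overlay channels: voxel sizes differ.")
  }
  structure(
    list(channels = setNames(list(a, b), c(a$channel, b$channel)),
         voxel_size = a$voxel_size),
    class = "multi_channel_volume"
  )
}

#' @export
print.multi_channel_volume <- function(x, ...) {
  cat(sprintf(
    "<multi_channel_volume> %d channels (%s), %.3g um/voxel\n",
    length(x$channels), paste(names(x$channels), collapse = ", "), x$voxel_size
  ))
  invisible(x)
}

#' Plot one slice of a voxel grid
#'
#' @param grid A `voxel_grid`.
#' @param slice Slice index along the long axis (default: middle slice).
#' @return A ggplot object.
#' @export
plot_slice <- function(grid, slice = NULL) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  slice <- slice %||% ((d[1] + 1L) %/% 2L)
  img <- grid$data[slice, , ]
  df <- tidyr::expand_grid(y = seq_len(d[2]), x = seq_len(d[3]))
  df$intensity <- as.vector(t(img)) # x fastest
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$intensity)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      title = sprintf("%s, slice %d", grid$channel, slice),
      x = "x (px)", y = "y (px)"
    )
}
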
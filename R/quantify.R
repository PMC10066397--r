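# Quantification: villous density on unfolded layers, follicle segmentation
# with volume and spacing statistics, and cell density per nuclei-mask area.

#' Villous density on an unfolded layer
#'
#' Detects villus apexes as local maxima of a scale-normalised
#' Laplacian-of-Gaussian response (bright blobs give positive peaks) with a
#' prominence floor and a minimum separation of about one villus width, then
#' bins the detections into square sectors.
#'
#' @param unfolded_layer Numeric matrix (slice x arc, or any 2D layer).
#' @param pixel_size Pixel size in micrometres.
#' @param sector_size Sector edge length in micrometres
#'   (>= `2 * pixel_size`).
#' @param min_prominence Minimum LoG response for a detection, in intensity
#'   units of the input layer.
#' @param sigma_um LoG scale; roughly half the expected villus width.
#' @param min_separation_um Minimum distance between detections (defaults to
#'   about one villus width, `2 * sigma_um`).
#' @return A `density_map`: list with `sectors` (tibble `row`, `col`,
#'   `count`, `density_per_mm2`), `maxima` (tibble `y`, `x`, `response`),
#'   `total_count`, `sector_size`, `pixel_size`, `density_per_mm2`
#'   (whole-image density) and `dim`.
#' @export
villous_density <- function(unfolded_layer, pixel_size, sector_size,
                            min_prominence, sigma_um = 2 * pixel_size,
                            min_separation_um = 2 * sigma_um) {
  if (!is.matrix(unfolded_layer) || !length(unfolded_layer)) {
    stop_parameter("`unfolded_layer` must be a non-empty matrix.")
  }
  if (sector_size < 2 * pixel_size) {
    stop_parameter("`sector_size` must be at least two pixels.")
  }
  nr <- nrow(unfolded_layer)
  nc <- ncol(unfolded_layer)

  maxima <- tibble(y = integer(), x = integer(), response = numeric())
  if (diff(range(unfolded_layer)) > 0) {
    s <- sigma_um / pixel_size
    h <- max(2L, as.integer(ceiling(3 * s)))
    u <- -h:h
    r2 <- outer(u^2, u^2, `+`)
    g <- exp(-r2 / (2 * s^2))
    # negative, scale-normalised LoG: positive response at bright blobs;
    # zero-mean kernel so a constant layer gives zero response
    knl <- (1 - r2 / (2 * s^2)) * g
    knl <- knl - mean(knl)
    knl <- knl / sum(knl[knl > 0]) # response in intensity units of the layer
    resp <- EBImage::filter2(unfolded_layer, knl, boundary = "replicate")

    # strict 8-neighbour local maximum (ties resolved by pixel order below)
    shift_ge <- matrix(TRUE, nr, nc)
    for (dy in -1:1) {
      for (dx in -1:1) {
        if (dy == 0 && dx == 0) next
        nb <- matrix(-Inf, nr, nc)
        ys <- seq_len(nr) + dy
        xs <- seq_len(nc) + dx
        oky <- ys >= 1 & ys <= nr
        okx <- xs >= 1 & xs <= nc
        nb[oky, okx] <- resp[ys[oky], xs[okx]]
        shift_ge <- shift_ge & (resp >= nb)
      }
    }
    cand <- which(shift_ge & resp >= min_prominence)
    if (length(cand)) {
      ri <- arrayInd(cand, c(nr, nc))
      ord <- order(-resp[cand], ri[, 1], ri[, 2])
      ri <- ri[ord, , drop = FALSE]
      rv <- resp[cand][ord]
      min_sep_px <- min_separation_um / pixel_size
      keep_y <- numeric(0)
      keep_x <- numeric(0)
      keep_r <- numeric(0)
      for (j in seq_len(nrow(ri))) {
        if (!length(keep_y) ||
          min((keep_y - ri[j, 1])^2 + (keep_x - ri[j, 2])^2) >= min_sep_px^2) {
          keep_y <- c(keep_y, ri[j, 1])
          keep_x <- c(keep_x, ri[j, 2])
          keep_r <- c(keep_r, rv[j])
        }
      }
      maxima <- tibble(y = as.integer(keep_y), x = as.integer(keep_x),
                       response = keep_r)
    }
  }

  n_srow <- max(1L, ceiling(nr * pixel_size / sector_size))
  n_scol <- max(1L, ceiling(nc * pixel_size / sector_size))
  sectors <- tidyr::expand_grid(row = seq_len(n_srow), col = seq_len(n_scol)) |>
    mutate(count = 0L)
  if (nrow(maxima)) {
    sr <- pmin(n_srow, floor((maxima$y - 0.5) * pixel_size / sector_size) + 1L)
    sc <- pmin(n_scol, floor((maxima$x - 0.5) * pixel_size / sector_size) + 1L)
    cnt <- dplyr::count(tibble(row = sr, col = sc), .data$row, .data$col)
    sectors <- sectors |>
      left_join(cnt, by = c("row", "col")) |>
      mutate(count = ifelse(is.na(.data$n), 0L, .data$n)) |>
      select("row", "col", "count")
  }
  sector_area_mm2 <- (sector_size * 1e-3)^2
  sectors <- mutate(sectors, density_per_mm2 = .data$count / sector_area_mm2)

  structure(
    list(
      sectors = sectors,
      maxima = maxima,
      total_count = nrow(maxima),
      sector_size = sector_size,
      pixel_size = pixel_size,
      density_per_mm2 = nrow(maxima) / (nr * nc * pixel_size^2 * 1e-6),
      dim = c(nr, nc)
    ),
    class = "density_map"
  )
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf(
    "<density_map> %d maxima over %d x %d px; %d sectors of %g um; %.1f per mm^2 overall\n",
    x$total_count, x$dim[1], x$dim[2], nrow(x$sectors), x$sector_size,
    x$density_per_mm2
  ))
  invisible(x)
}

#' @export
tidy.density_map <- function(x, ...) x$sectors

#' @export
glance.density_map <- function(x, ...) {
  tibble(
    total_count = x$total_count,
    density_per_mm2 = x$density_per_mm2,
    n_sectors = nrow(x$sectors),
    sector_size_um = x$sector_size
  )
}

#' @export
autoplot.density_map <- function(object, ...) {
  ggplot2::ggplot(object$sectors,
                  ggplot2::aes(.data$col, .data$row, fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = sprintf("arc sector (%g um)", object$sector_size),
      y = sprintf("axial sector (%g um)", object$sector_size),
      fill = "villi", title = "Villous density per sector"
    )
}

#' Segment follicles in the marker channel
#'
#' Gaussian smoothing at a fixed physical scale, absolute-intensity
#' thresholding, 26-connected component labelling and removal of components
#' below a voxel-count cutoff. Volumes are `voxel_count * voxel_size^3` and
#' centroids are voxel-centre means in micrometres.
#'
#' @param marker A `voxel_grid` (marker channel).
#' @param intensity_threshold Absolute threshold, inside the volume's
#'   intensity range.
#' @param smoothing_sigma_um Gaussian sigma in micrometres (default 2).
#' @param min_voxels Minimum component size kept.
#' @return A `follicle_table`: tibble with columns `label`, `voxel_count`,
#'   `volume_um3`, `centroid_z_um`, `centroid_y_um`, `centroid_x_um`, sorted
#'   by decreasing size; attributes record the parameters.
#' @export
segment_follicles <- function(marker, intensity_threshold,
                              smoothing_sigma_um = 2, min_voxels = 1L) {
  stopifnot(inherits(marker, "voxel_grid"))
  rng <- range(marker$data)
  if (intensity_threshold <= rng[1] || intensity_threshold >= rng[2]) {
    stop_parameter(sprintf(
      "intensity_threshold %.4g is outside the volume's intensity range [%.4g, %.4g].",
      intensity_threshold, rng[1], rng[2]
    ))
  }
  vox <- marker$voxel_size
  sm <- gauss_blur_3d(marker$data, smoothing_sigma_um / vox)
  bw <- sm > intensity_threshold
  lab <- label_components_3d(bw)

  tab <- tabulate(lab[lab > 0L])
  keep <- which(tab >= min_voxels)
  out <- if (length(keep)) {
    idx <- which(lab > 0L)
    memb <- lab[idx]
    sel <- memb %in% keep
    idx <- idx[sel]
    memb <- memb[sel]
    co <- arrayInd(idx, dim(marker$data))
    tibble(
      old = memb,
      z = (co[, 1] - 0.5) * vox,
      y = (co[, 2] - 0.5) * vox,
      x = (co[, 3] - 0.5) * vox
    ) |>
      group_by(.data$old) |>
      summarise(
        voxel_count = dplyr::n(),
        centroid_z_um = mean(.data$z),
        centroid_y_um = mean(.data$y),
        centroid_x_um = mean(.data$x),
        .groups = "drop"
      ) |>
      arrange(dplyr::desc(.data$voxel_count)) |>
      mutate(
        label = dplyr::row_number(),
        volume_um3 = .data$voxel_count * vox^3
      ) |>
      select("label", "voxel_count", "volume_um3",
             "centroid_z_um", "centroid_y_um", "centroid_x_um")
  } else {
    tibble(
      label = integer(), voxel_count = integer(), volume_um3 = numeric(),
      centroid_z_um = numeric(), centroid_y_um = numeric(),
      centroid_x_um = numeric()
    )
  }
  structure(
    out,
    class = c("follicle_table", class(out)),
    threshold = intensity_threshold,
    smoothing_sigma_um = smoothing_sigma_um,
    min_voxels = as.integer(min_voxels),
    voxel_size = vox
  )
}

#' @export
tidy.follicle_table <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(unclass(x))]) # strip attributes
}

#' @export
glance.follicle_table <- function(x, ...) {
  tibble(
    n_follicles = nrow(x),
    total_volume_um3 = sum(x$volume_um3),
    threshold = attr(x, "threshold"),
    smoothing_sigma_um = attr(x, "smoothing_sigma_um"),
    min_voxels = attr(x, "min_voxels"),
    voxel_size = attr(x, "voxel_size")
  )
}

#' Inter-follicle spacing statistics
#'
#' Centroid-to-centroid Euclidean distances. In the default `"all_pairs"`
#' mode each follicle reports the minimum, mean and maximum distance to every
#' other follicle; `"axial_nn"` reports the axial (long-axis) distance to the
#' nearest axial neighbour in all three columns.
#'
#' @param table A `follicle_table` (or any tibble with centroid columns) with
#'   at least two rows.
#' @param mode `"all_pairs"` (default) or `"axial_nn"`.
#' @return A `follicle_stats` tibble: `label`, `min_distance_um`,
#'   `mean_distance_um`, `max_distance_um`.
#' @export
follicle_stats <- function(table, mode = c("all_pairs", "axial_nn")) {
  mode <- match.arg(mode)
  if (nrow(table) < 2) {
    abort("at least two follicles are required for spacing statistics.",
      class = "gutopt_insufficient_objects_error"
    )
  }
  cen <- cbind(table$centroid_z_um, table$centroid_y_um, table$centroid_x_um)
  if (mode == "all_pairs") {
    d <- as.matrix(dist(cen))
    diag(d) <- NA
    out <- tibble(
      label = table$label,
      min_distance_um = unname(apply(d, 1, min, na.rm = TRUE)),
      mean_distance_um = unname(apply(d, 1, mean, na.rm = TRUE)),
      max_distance_um = unname(apply(d, 1, max, na.rm = TRUE))
    )
  } else {
    dz <- abs(outer(cen[, 1], cen[, 1], `-`))
    diag(dz) <- NA
    nn <- unname(apply(dz, 1, min, na.rm = TRUE))
    out <- tibble(
      label = table$label,
      min_distance_um = nn, mean_distance_um = nn, max_distance_um = nn
    )
  }
  structure(out, class = c("follicle_stats", class(out)), mode = mode)
}

#' @export
tidy.follicle_stats <- function(x, ...) {
  as_tibble(unclass(x)[seq_along(unclass(x))])
}

#' @export
glance.follicle_stats <- function(x, ...) {
  tibble(
    n_follicles = nrow(x),
    mean_nn_distance_um = mean(x$min_distance_um),
    mode = attr(x, "mode")
  )
}

#' @export
autoplot.follicle_stats <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$label))) +
    ggplot2::geom_linerange(ggplot2::aes(
      ymin = .data$min_distance_um, ymax = .data$max_distance_um
    )) +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_distance_um)) +
    ggplot2::labs(
      x = "follicle", y = "distance to other follicles (um)",
      title = "Inter-follicle spacing (min / mean / max)"
    )
}

#' Cell density per nuclei-mask area
#'
#' @param cell_coords Tibble/data frame with columns `x_um`, `y_um` (volume
#'   frame with the origin at the image corner), or a two-column matrix.
#' @param nuclei_mask Logical matrix (rows = y, cols = x) defining the tissue
#'   area.
#' @param pixel_size Pixel size in micrometres.
#' @return Density in cells per mm^2 (cells falling inside the mask, divided
#'   by the mask area).
#' @export
cell_density <- function(cell_coords, nuclei_mask, pixel_size) {
  if (!any(nuclei_mask)) {
    abort("nuclei mask is empty: density undefined.",
      class = "gutopt_undefined_density_error"
    )
  }
  if (is.matrix(cell_coords)) {
    cell_coords <- tibble(x_um = cell_coords[, 1], y_um = cell_coords[, 2])
  }
  area_mm2 <- sum(nuclei_mask) * pixel_size^2 * 1e-6
  if (nrow(cell_coords) == 0) {
    return(0)
  }
  ri <- pmax(1L, pmin(nrow(nuclei_mask), floor(cell_coords$y_um / pixel_size) + 1L))
  ci <- pmax(1L, pmin(ncol(nuclei_mask), floor(cell_coords$x_um / pixel_size) + 1L))
  in_img <- cell_coords$y_um >= 0 & cell_coords$y_um <= nrow(nuclei_mask) * pixel_size &
    cell_coords$x_um >= 0 & cell_coords$x_um <= ncol(nuclei_mask) * pixel_size
  inside <- sum(nuclei_mask[cbind(ri, ci)] & in_img)
  inside / area_mm2
}

#' Is a signal density visible in OPT?
#'
#' Structures are resolvable in OPT reconstructions above a signal density of
#' about 400 fluorescent cells per mm^2 of nuclei signal; the comparison is
#' inclusive and the threshold configurable.
#'
#' @param density Cell density in cells/mm^2 (non-negative).
#' @param threshold Visibility threshold, cells/mm^2 (default 400).
#' @return `TRUE` iff `density >= threshold`.
#' @export
opt_visible <- function(density, threshold = 400) {
  if (any(density < 0)) stop_parameter("`density` must be non-negative.")
  density >= threshold
}
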
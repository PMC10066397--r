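# Multi-page TIFF volume IO with JSON sidecars, and CSV export of tables.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a voxel grid as a multi-page TIFF
#'
#' One page per slice (axis 1). Intensities are clipped to [0, 1] and stored
#' as 16-bit; a JSON sidecar (`<path>.json`) records the voxel size, channel
#' label and dimensions, making the round trip through [read_volume()]
#' lossless for 16-bit data.
#'
#' @param grid A `voxel_grid`.
#' @param path Output TIFF filename.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "voxel_grid"))
  d <- dim(grid$data)
  pages <- purrr::map(seq_len(d[1]), function(k) {
    m <- grid$data[k, , ]
    round(pmin(pmax(m, 0), 1) * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(
      voxel_size_um = grid$voxel_size,
      channel = grid$channel,
      dim = d
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a voxel grid from a multi-page TIFF
#'
#' Page index becomes axis 1 (the sample long axis). The voxel size comes
#' from the JSON sidecar written by [write_volume()], or from the
#' `voxel_size` argument when no sidecar exists.
#'
#' @param path TIFF filename.
#' @param voxel_size Voxel size in micrometres; required when there is no
#'   sidecar.
#' @return A `voxel_grid`.
#' @export
read_volume <- function(path, voxel_size = NULL) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  shapes <- unique(purrr::map(pages, dim))
  if (length(shapes) != 1) {
    stop_parameter("TIFF pages have inconsistent shapes.")
  }
  channel <- "unlabelled"
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    voxel_size <- voxel_size %||% as.numeric(meta$voxel_size_um)
    channel <- meta$channel %||% channel
  }
  if (is.null(voxel_size)) {
    abort(
      "no voxel size: provide `voxel_size` or a JSON sidecar next to the TIFF.",
      class = "gutopt_metadata_error"
    )
  }
  d <- shapes[[1]]
  vol <- array(0, c(length(pages), d[1], d[2]))
  for (k in seq_along(pages)) vol[k, , ] <- pages[[k]]
  voxel_grid(vol, voxel_size, channel)
}

#' Write a projection set as a multi-page TIFF
#'
#' One page per angle; the sidecar stores the angles and detector pitch.
#'
#' @param ps A `projection_set`.
#' @param path Output TIFF filename.
#' @param scale Intensity scale mapped to the 16-bit maximum (defaults to the
#'   data maximum).
#' @return `path`, invisibly.
#' @export
write_projections <- function(ps, path, scale = NULL) {
  stopifnot(inherits(ps, "projection_set"))
  scale <- scale %||% max(ps$projections, 1e-12)
  d <- dim(ps$projections)
  pages <- purrr::map(seq_len(d[1]), function(a) {
    round(pmin(pmax(ps$projections[a, , ] / scale, 0), 1) * 65535) / 65535
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(
      angles_deg = ps$angles_deg,
      detector_pixel_size_um = ps$detector_pixel_size,
      channel = ps$channel,
      intensity_scale = scale,
      dim = d
    ),
    sidecar_path(path),
    auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' Read a projection set written by [write_projections()]
#'
#' @param path TIFF filename (sidecar required).
#' @return A `projection_set`.
#' @export
read_projections <- function(path) {
  sc <- sidecar_path(path)
  if (!file.exists(sc)) {
    abort("projection sets require their JSON sidecar.",
      class = "gutopt_metadata_error"
    )
  }
  meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  d <- dim(pages[[1]])
  proj <- array(0, c(length(pages), d[1], d[2]))
  for (a in seq_along(pages)) proj[a, , ] <- pages[[a]] * meta$intensity_scale
  projection_set(
    proj, as.numeric(meta$angles_deg),
    as.numeric(meta$detector_pixel_size_um), meta$channel
  )
}

#' Export phantom ground truth as CSV tables plus a JSON sidecar
#'
#' @param truth A `phantom_truth`.
#' @param dir Output directory (created if missing).
#' @param spec Optional [phantom_spec()] stored alongside as JSON.
#' @return `dir`, invisibly.
#' @export
write_truth <- function(truth, dir, spec = NULL) {
  stopifnot(inherits(truth, "phantom_truth"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(truth$villus_apexes, file.path(dir, "villus_apexes.csv"))
  readr::write_csv(truth$follicles, file.path(dir, "follicles.csv"))
  readr::write_csv(truth$cells, file.path(dir, "cells.csv"))
  jsonlite::write_json(as.list(truth$layer_radii),
    file.path(dir, "layer_radii.json"),
    auto_unbox = TRUE, digits = NA
  )
  if (!is.null(spec)) {
    sp <- unclass(spec)
    sp$follicle_specs <- as.data.frame(sp$follicle_specs)
    sp$cell_specs <- as.data.frame(sp$cell_specs)
    jsonlite::write_json(sp, file.path(dir, "phantom_spec.json"),
      auto_unbox = TRUE, digits = NA, dataframe = "rows"
    )
  }
  invisible(dir)
}
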
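# Reverse-OPT bookkeeping: map regions of interest selected in the 3D
# reconstruction onto physical cryosection indices, and match section-level
# observations back to the OPT ROIs.

#' Cryosectioning plan
#'
#' @param section_thickness Section thickness in micrometres (default 25).
#' @param sample_length Sample length along the cutting axis, micrometres.
#' @param origin_end Which end of the sample the cutting starts from.
#' @return A `section_plan` list.
#' @export
section_plan <- function(section_thickness = 25, sample_length,
                         origin_end = c("proximal", "distal")) {
  origin_end <- match.arg(origin_end)
  if (section_thickness <= 0) stop_parameter("`section_thickness` must be positive.")
  if (sample_length < section_thickness) {
    stop_parameter("`sample_length` must be at least one section thickness.")
  }
  structure(
    list(
      section_thickness = section_thickness,
      sample_length = sample_length,
      origin_end = origin_end
    ),
    class = "section_plan"
  )
}

#' Axial extent of a reconstruction ROI
#'
#' Converts the slice span of a voxel ROI into physical distances from the
#' configured origin end of the tissue. With the origin at the proximal end
#' (slice 1), a ROI spanning 1-based slices `i..j` has the half-open extent
#' `((i - 1) * voxel_size, j * voxel_size)`; with the origin at the distal
#' end the extent is mirrored so that proximal and distal extents of the same
#' ROI always sum to the sample length.
#'
#' @param volume_shape Integer vector `(slices, rows, cols)`.
#' @param voxel_size Voxel size in micrometres.
#' @param roi_voxels Matrix of 1-based voxel indices (columns `slice`, `row`,
#'   `col`; extra columns ignored) or a vector of slice indices.
#' @param origin_end `"proximal"` (slice 1) or `"distal"`.
#' @param roi_id Identifier stored in the record.
#' @return A `roi_record` tibble row: `roi_id`, `start_um`, `end_um`,
#'   `centroid_z_um`, `source`.
#' @export
roi_axial_distance <- function(volume_shape, voxel_size, roi_voxels,
                               origin_end = c("proximal", "distal"),
                               roi_id = 1L) {
  origin_end <- match.arg(origin_end)
  if (is.vector(roi_voxels)) roi_voxels <- cbind(roi_voxels)
  if (nrow(roi_voxels) == 0) {
    abort("ROI voxel set is empty.", class = "gutopt_parameter_error")
  }
  sl <- roi_voxels[, 1]
  nz <- volume_shape[1]
  if (any(sl < 1 | sl > nz)) {
    stop_geometry("ROI slice indices fall outside the volume.")
  }
  start <- (min(sl) - 1) * voxel_size
  end <- max(sl) * voxel_size
  cz <- mean(sl - 0.5) * voxel_size
  len <- nz * voxel_size
  if (origin_end == "distal") {
    tmp <- start
    start <- len - end
    end <- len - tmp
    cz <- len - cz
  }
  tibble(
    roi_id = roi_id, start_um = start, end_um = end,
    centroid_z_um = cz, source = "opt"
  )
}

#' Section indices covering a ROI
#'
#' Zero-based indices `k` of the half-open section intervals
#' `[k * t, (k + 1) * t)` that intersect the half-open ROI extent
#' `[start, end)`, with `t` the section thickness.
#'
#' @param roi A `roi_record` row (needs `start_um`, `end_um`).
#' @param plan A [section_plan()].
#' @return Integer vector of zero-based section indices.
#' @export
section_indices <- function(roi, plan) {
  stopifnot(inherits(plan, "section_plan"))
  start <- roi$start_um
  end <- roi$end_um
  if (start < 0 || end > plan$sample_length || start >= end) {
    stop_geometry("ROI extent falls outside the sample length.")
  }
  t <- plan$section_thickness
  k_min <- floor(start / t)
  k_max <- ceiling(end / t) - 1
  as.integer(seq(k_min, k_max))
}

#' Match high-density sections to OPT ROIs
#'
#' Assigns each high-density section to the OPT ROI whose section-index
#' window contains it; report-only semantics (no errors for misses).
#'
#' @param opt_rois Tibble of `roi_record` rows.
#' @param section_hits Tibble with columns `section_index` (zero-based) and
#'   `density` (cells/mm^2).
#' @param plan A [section_plan()].
#' @param density_threshold Density above which a section counts as a hit
#'   (inclusive; default 400 cells/mm^2).
#' @return A `revopt_match`: list with `assignments` (tibble `section_index`,
#'   `density`, `roi_id`, NA where unexplained), `unexplained_sections`,
#'   `empty_rois`.
#' @export
match_sections <- function(opt_rois, section_hits, plan, density_threshold = 400) {
  stopifnot(inherits(plan, "section_plan"))
  windows <- purrr::map(seq_len(nrow(opt_rois)), function(i) {
    section_indices(opt_rois[i, ], plan)
  })
  hits <- filter(section_hits, opt_visible(.data$density, density_threshold))
  roi_of <- purrr::map_int(hits$section_index, function(k) {
    j <- which(purrr::map_lgl(windows, ~ k %in% .x))
    if (length(j)) as.integer(opt_rois$roi_id[j[1]]) else NA_integer_
  })
  assignments <- mutate(hits, roi_id = roi_of)
  matched_rois <- unique(roi_of[!is.na(roi_of)])
  structure(
    list(
      assignments = assignments,
      unexplained_sections = assignments$section_index[is.na(assignments$roi_id)],
      empty_rois = setdiff(opt_rois$roi_id, matched_rois)
    ),
    class = "revopt_match"
  )
}

#' @export
print.revopt_match <- function(x, ...) {
  cat(sprintf(
    "<revopt_match> %d high-density sections, %d unexplained, %d ROIs without hits\n",
    nrow(x$assignments), length(x$unexplained_sections), length(x$empty_rois)
  ))
  invisible(x)
}

#' @export
tidy.revopt_match <- function(x, ...) x$assignments
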
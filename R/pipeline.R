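# End-to-end pipeline driver: phantom -> simulate -> reconstruct -> unfold ->
# quantify -> revopt, with a nested key-value configuration, per-stage
# toggles, artifact writing and a machine-readable run report.

#' Default pipeline configuration
#'
#' Nested list of stage parameters; every stage has an `enabled` toggle. When
#' the simulate/reconstruct stages are disabled, downstream stages run on the
#' phantom volumes directly.
#'
#' @param out_dir Output directory for artifacts.
#' @param seed Integer seed controlling all randomness in the run.
#' @return A `pipeline_config` list.
#' @export
default_pipeline_config <- function(out_dir = tempfile("gutopt_run_"), seed = 1L) {
  structure(
    list(
      seed = as.integer(seed),
      out_dir = out_dir,
      phantom = list(
        enabled = TRUE,
        grid_shape = c(128L, 64L, 64L),
        voxel_size = 10,
        lumen_radius = 120,
        mucosa_outer_radius = 180,
        submucosa_outer_radius = 215,
        muscularis_outer_radius = 240,
        villus_count_per_ring = 12L,
        villus_length = 50,
        villus_width = 40,
        villus_axial_period = 160,
        noise_sigma = 0.005
      ),
      simulate = list(enabled = TRUE, n_angles = 400L),
      reconstruct = list(enabled = TRUE, window = "ramlak"),
      unfold = list(
        enabled = TRUE, angle_deg = 45, band_inner = 200, band_outer = 20,
        step = NULL
      ),
      quantify = list(
        enabled = TRUE,
        villous_sector_size = 320,
        villous_min_prominence = 0.15,
        villous_sigma_um = 30,
        villous_min_separation = 90,
        follicle_threshold = 0.3,
        follicle_smoothing_sigma_um = 2,
        follicle_min_voxels = 50L
      ),
      revopt = list(
        enabled = TRUE, section_thickness = 25, origin_end = "proximal"
      )
    ),
    class = "pipeline_config"
  )
}

# Follicles for the pipeline phantom: three objects on the submucosal ring at
# 1/4, 1/2 and 3/4 of the sample length, volumes ~1-2.5 million um^3.
pipeline_follicle_specs <- function(p) {
  cy <- p$grid_shape[2] * p$voxel_size / 2
  cx <- p$grid_shape[3] * p$voxel_size / 2
  ring <- (p$mucosa_outer_radius + p$submucosa_outer_radius) / 2
  len <- p$grid_shape[1] * p$voxel_size
  ang <- c(0, 2 * pi / 3, 4 * pi / 3)
  tibble(
    z_um = len * c(0.25, 0.5, 0.75),
    y_um = cy - ring * sin(ang),
    x_um = cx + ring * cos(ang),
    a_um = c(70, 80, 90),
    b_um = c(65, 75, 85),
    c_um = c(55, 65, 75),
    peak = c(0.9, 0.85, 0.95)
  )
}

#' Validate a pipeline configuration
#'
#' Rejects unknown keys (at the top level and within stages) before any work
#' is done; missing keys fall back to the defaults.
#'
#' @param config Nested list, typically edited from
#'   [default_pipeline_config()] or read from YAML via [read_pipeline_config()].
#' @return The merged, validated `pipeline_config`.
#' @export
validate_pipeline_config <- function(config) {
  template <- default_pipeline_config()
  bad <- setdiff(names(config), names(template))
  if (length(bad)) {
    abort(sprintf("unknown configuration key(s): %s", paste(bad, collapse = ", ")),
      class = "gutopt_config_error"
    )
  }
  merged <- template
  for (key in names(config)) {
    if (is.list(template[[key]])) {
      badsub <- setdiff(names(config[[key]]), names(template[[key]]))
      if (length(badsub)) {
        abort(
          sprintf(
            "unknown configuration key(s) in '%s': %s",
            key, paste(badsub, collapse = ", ")
          ),
          class = "gutopt_config_error"
        )
      }
      for (sub in names(config[[key]])) merged[[key]][[sub]] <- config[[key]][[sub]]
    } else {
      merged[[key]] <- config[[key]]
    }
  }
  class(merged) <- "pipeline_config"
  merged
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file mirroring [default_pipeline_config()].
#' @return A validated `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  validate_pipeline_config(yaml::read_yaml(path))
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order (phantom, simulate, reconstruct,
#' unfold, quantify, revopt), writes artifacts (TIFF volumes, CSV tables) and
#' a JSON run report with stage timings, counts, parameters and the seed.
#' Deterministic for a fixed seed. A stage failure aborts with the stage name
#' and cause; artifacts of completed stages are retained.
#'
#' @param config A `pipeline_config` (validated with
#'   [validate_pipeline_config()]; plain lists are validated here).
#' @param write_artifacts Write TIFF/CSV artifacts (default `TRUE`; the
#'   report is always returned).
#' @return The run report, invisibly a list (also written to
#'   `<out_dir>/report.json` when artifacts are enabled).
#' @export
run_pipeline <- function(config = default_pipeline_config(), write_artifacts = TRUE) {
  config <- validate_pipeline_config(unclass(config))
  out_dir <- config$out_dir
  if (write_artifacts) dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  report <- list(seed = config$seed, parameters = unclass(config), stages = list())
  state <- new.env(parent = emptyenv())

  run_stage <- function(name, fun) {
    t0 <- Sys.time()
    res <- tryCatch(fun(), error = function(e) {
      abort(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
        class = "gutopt_stage_error", parent = e
      )
    })
    report$stages[[name]] <<- c(
      list(elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
      res
    )
  }

  cfg <- config
  withr::with_seed(cfg$seed, {
    if (cfg$phantom$enabled) {
      run_stage("phantom", function() {
        p <- cfg$phantom
        spec <- phantom_spec(
          grid_shape = p$grid_shape, voxel_size = p$voxel_size,
          lumen_radius = p$lumen_radius,
          mucosa_outer_radius = p$mucosa_outer_radius,
          submucosa_outer_radius = p$submucosa_outer_radius,
          muscularis_outer_radius = p$muscularis_outer_radius,
          villus_count_per_ring = p$villus_count_per_ring,
          villus_length = p$villus_length, villus_width = p$villus_width,
          villus_axial_period = p$villus_axial_period,
          follicle_specs = pipeline_follicle_specs(p),
          noise_sigma = p$noise_sigma,
          rng_seed = cfg$seed
        )
        ph <- make_gut_phantom(spec)
        state$phantom <- ph
        if (write_artifacts) {
          write_volume(ph$autofluorescence, file.path(out_dir, "autofluorescence.tif"))
          write_volume(ph$marker, file.path(out_dir, "marker.tif"))
          write_truth(ph$truth, file.path(out_dir, "truth"), spec)
        }
        list(
          n_villus_apexes = nrow(ph$truth$villus_apexes),
          n_follicles = nrow(ph$truth$follicles),
          n_cells = nrow(ph$truth$cells)
        )
      })
    }

    if (cfg$simulate$enabled) {
      run_stage("simulate", function() {
        state$proj_auto <- forward_project(
          state$phantom$autofluorescence, cfg$simulate$n_angles
        )
        state$proj_marker <- forward_project(
          state$phantom$marker, cfg$simulate$n_angles
        )
        if (write_artifacts) {
          write_projections(state$proj_auto, file.path(out_dir, "projections_auto.tif"))
          write_projections(state$proj_marker, file.path(out_dir, "projections_marker.tif"))
        }
        list(n_angles = cfg$simulate$n_angles)
      })
    }

    if (cfg$reconstruct$enabled) {
      run_stage("reconstruct", function() {
        state$recon_auto <- reconstruct_fbp(state$proj_auto, cfg$reconstruct$window)
        state$recon_marker <- reconstruct_fbp(state$proj_marker, cfg$reconstruct$window)
        state$overlay <- overlay_channels(state$recon_auto, state$recon_marker)
        if (write_artifacts) {
          write_volume(state$recon_auto, file.path(out_dir, "recon_autofluorescence.tif"))
          write_volume(state$recon_marker, file.path(out_dir, "recon_marker.tif"))
        }
        list(window = cfg$reconstruct$window)
      })
    }

    auto_vol <- if (cfg$reconstruct$enabled) state$recon_auto else state$phantom$autofluorescence
    marker_vol <- if (cfg$reconstruct$enabled) state$recon_marker else state$phantom$marker

    if (cfg$unfold$enabled) {
      run_stage("unfold", function() {
        u <- cfg$unfold
        state$unfold <- unfold_volume(
          auto_vol,
          angle_deg = u$angle_deg,
          band_inner = u$band_inner, band_outer = u$band_outer,
          step = u$step %||% auto_vol$voxel_size
        )
        if (write_artifacts) {
          readr::write_csv(state$unfold$seams, file.path(out_dir, "seams.csv"))
        }
        list(
          n_slices_ok = sum(state$unfold$seams$ok),
          mean_perimeter_um = mean(state$unfold$seams$perimeter_um, na.rm = TRUE)
        )
      })
    }

    if (cfg$quantify$enabled) {
      run_stage("quantify", function() {
        q <- cfg$quantify
        out <- list()
        if (!is.null(state$unfold)) {
          tip_depth <- cfg$phantom$muscularis_outer_radius -
            (cfg$phantom$lumen_radius - cfg$phantom$villus_length / 2)
          layer <- unfolded_layer(state$unfold, tip_depth)
          dm <- villous_density(
            layer,
            pixel_size = auto_vol$voxel_size,
            sector_size = q$villous_sector_size,
            min_prominence = q$villous_min_prominence,
            sigma_um = q$villous_sigma_um,
            min_separation_um = q$villous_min_separation
          )
          state$density <- dm
          if (write_artifacts) {
            readr::write_csv(dm$sectors, file.path(out_dir, "villous_density.csv"))
          }
          out$villus_count <- dm$total_count
        }
        ft <- segment_follicles(
          marker_vol,
          intensity_threshold = q$follicle_threshold,
          smoothing_sigma_um = q$follicle_smoothing_sigma_um,
          min_voxels = q$follicle_min_voxels
        )
        state$follicles <- ft
        if (write_artifacts) {
          readr::write_csv(tidy(ft), file.path(out_dir, "follicles.csv"))
        }
        out$n_follicles <- nrow(ft)
        if (nrow(ft) >= 2) {
          fs <- follicle_stats(ft)
          state$follicle_stats <- fs
          if (write_artifacts) {
            readr::write_csv(tidy(fs), file.path(out_dir, "follicle_stats.csv"))
          }
          out$mean_nn_distance_um <- mean(fs$min_distance_um)
        }
        out
      })
    }

    if (cfg$revopt$enabled) {
      run_stage("revopt", function() {
        vox <- marker_vol$voxel_size
        d <- dim(marker_vol$data)
        plan <- section_plan(
          section_thickness = cfg$revopt$section_thickness,
          sample_length = d[1] * vox,
          origin_end = cfg$revopt$origin_end
        )
        ft <- state$follicles
        rois <- purrr::map(seq_len(nrow(ft)), function(i) {
          half <- (3 * ft$volume_um3[i] / (4 * pi))^(1 / 3)
          z0 <- max(1L, floor((ft$centroid_z_um[i] - half) / vox) + 1L)
          z1 <- min(d[1], ceiling((ft$centroid_z_um[i] + half) / vox))
          roi_axial_distance(d, vox, cbind(z0:z1),
            origin_end = cfg$revopt$origin_end, roi_id = ft$label[i]
          )
        }) |> bind_rows()
        windows <- purrr::map(seq_len(nrow(rois)), function(i) {
          section_indices(rois[i, ], plan)
        })
        state$rois <- rois
        if (write_artifacts) {
          readr::write_csv(rois, file.path(out_dir, "rois.csv"))
          win_tbl <- tibble(
            roi_id = rep(rois$roi_id, lengths(windows)),
            section_index = unlist(windows)
          )
          readr::write_csv(win_tbl, file.path(out_dir, "section_windows.csv"))
        }
        list(
          n_rois = nrow(rois),
          n_sections_total = as.integer(floor(plan$sample_length / plan$section_thickness))
        )
      })
    }
  })

  # truth cross-check for the report
  if (!is.null(state$phantom) && !is.null(state$follicles)) {
    report$checks <- list(
      follicle_count_truth = nrow(state$phantom$truth$follicles),
      follicle_count_measured = nrow(state$follicles)
    )
  }

  if (write_artifacts) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
      auto_unbox = TRUE, digits = NA, force = TRUE
    )
  }
  invisible(report)
}
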
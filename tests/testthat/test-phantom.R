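test_that("marker channel is empty when no follicles or cells are specified", {
  spec <- phantom_spec(
    grid_shape = c(8L, 80L, 80L), noise_sigma = 0,
    follicle_specs = empty_follicles()
  )
  ph <- make_gut_phantom(spec)
  expect_identical(max(abs(ph$marker$data)), 0)
})

test_that("ground truth reports the analytic ellipsoid volume", {
  fs <- tibble::tibble(
    z_um = 400, y_um = 400, x_um = 400,
    a_um = 100, b_um = 100, c_um = 100, peak = 0.9
  )
  spec <- phantom_spec(
    grid_shape = c(80L, 80L, 80L), noise_sigma = 0, follicle_specs = fs
  )
  ph <- make_gut_phantom(spec)
  expect_equal(ph$truth$follicles$volume_um3, 4 / 3 * pi * 1e6)
  # sphere with r = 100 um
  expect_equal(ph$truth$follicles$volume_um3, 4.18879e6, tolerance = 1e-5)
})

test_that("phantom generation is deterministic under a fixed seed", {
  spec <- phantom_spec(grid_shape = c(16L, 80L, 80L), noise_sigma = 0.05)
  a <- make_gut_phantom(spec)
  b <- make_gut_phantom(spec)
  expect_identical(a$autofluorescence$data, b$autofluorescence$data)
  expect_identical(a$marker$data, b$marker$data)
})

test_that("invalid phantom geometry is rejected with a geometry error", {
  expect_error(
    phantom_spec(lumen_radius = 250, mucosa_outer_radius = 220),
    class = "gutopt_geometry_error"
  )
  expect_error(
    phantom_spec(muscularis_outer_radius = 500),
    class = "gutopt_geometry_error"
  )
  expect_error(
    phantom_spec(follicle_specs = tibble::tibble(
      z_um = 1e5, y_um = 400, x_um = 400, a_um = 50, b_um = 50, c_um = 50,
      peak = 0.9
    )),
    class = "gutopt_geometry_error"
  )
  expect_error(
    phantom_spec(follicle_specs = tibble::tibble(
      z_um = 400, y_um = 400, x_um = 400, a_um = 5, b_um = 50, c_um = 50,
      peak = 0.9
    )),
    class = "gutopt_geometry_error" # semi-axis below 2 voxels
  )
})

test_that("rendered structure counts match the phantom spec exactly", {
  # follicles only: one component per follicle on the noiseless marker
  fs <- default_follicle_specs(c(96L, 80L, 80L), 10)
  spec <- phantom_spec(
    grid_shape = c(96L, 80L, 80L), noise_sigma = 0, follicle_specs = fs
  )
  ph <- make_gut_phantom(spec)
  expect_identical(nrow(ph$truth$follicles), nrow(fs))
  lab <- gutopt:::label_components_3d(ph$marker$data > 0.2)
  expect_identical(as.integer(max(lab)), nrow(fs))

  # cells only: one component per cell
  spec2 <- phantom_spec(
    grid_shape = c(96L, 80L, 80L), noise_sigma = 0,
    follicle_specs = empty_follicles(),
    cell_specs = tibble::tibble(region = "muscularis", count = 3L)
  )
  ph2 <- make_gut_phantom(spec2)
  expect_identical(nrow(ph2$truth$cells), 3L)
  lab2 <- gutopt:::label_components_3d(ph2$marker$data > 0.2)
  expect_identical(as.integer(max(lab2)), 3L)
})

test_that("tissue layers occur in anatomical order along radial rays", {
  spec <- phantom_spec(
    grid_shape = c(4L, 80L, 80L), noise_sigma = 0,
    follicle_specs = empty_follicles()
  )
  ph <- make_gut_phantom(spec)
  sl <- ph$autofluorescence$data[2, , ]
  centre <- 40.5
  layer_vals <- c(lumen = 0.02, mucosa = 0.9, submucosa = 0.55, muscularis = 0.75)
  for (ang in c(10, 100, 200, 300) * pi / 180) {
    r_steps <- seq(0, 38, by = 0.5)
    ray_rows <- centre - r_steps * sin(ang)
    ray_cols <- centre + r_steps * cos(ang)
    vals <- sl[cbind(pmin(80, pmax(1, round(ray_rows))), pmin(80, pmax(1, round(ray_cols))))]
    first_at <- vapply(layer_vals, function(v) {
      ix <- which(abs(vals - v) < 1e-9)
      if (length(ix)) min(ix) else NA_integer_
    }, integer(1))
    expect_false(any(is.na(first_at)))
    expect_true(all(diff(first_at) > 0))
  }
})

test_that("annulus phantom matches its analytic area and symmetry", {
  ann <- make_annulus_phantom(80, 120, c(2L, 256L, 256L), 1)
  sl <- ann$data[1, , ]
  analytic <- pi * (120^2 - 80^2)
  expect_lt(abs(sum(sl) - analytic) / analytic, 0.02)
  # 90 degree rotation leaves the mask unchanged
  expect_identical(rot90_exact(sl), sl)
  # degenerate annulus: filled disk
  disk <- make_annulus_phantom(0, 60, c(1L, 128L, 128L), 1)
  expect_lt(abs(sum(disk$data) - pi * 60^2) / (pi * 60^2), 0.02)
  expect_error(make_annulus_phantom(50, 40), class = "gutopt_geometry_error")
  expect_error(make_annulus_phantom(10, 200, c(1L, 64L, 64L), 1),
    class = "gutopt_geometry_error"
  )
})

test_that("synthetic sections report the exact requested cell density", {
  s <- make_section_image(400, 1.0, 10, seed = 3)
  expect_equal(s$truth$density_per_mm2, 400)
  expect_equal(s$truth$mask_area_mm2, 1.0)
  expect_identical(nrow(s$truth$cells), 400L)

  s0 <- make_section_image(0, 0.5, 10, seed = 3)
  expect_equal(s0$truth$density_per_mm2, 0)

  s4 <- make_section_image(100, 0.25, 10, seed = 3)
  expect_equal(s4$truth$density_per_mm2, 400)

  expect_error(make_section_image(1e6, 0.01, 10), class = "gutopt_geometry_error")
})
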
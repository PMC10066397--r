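# The villous fixtures are shared across blocks: one noiseless and one noisy
# phantom with exactly 60 villus apexes (5 rings x 12 villi).

uf_clean <- unfold_volume(
  make_gut_phantom(villous_phantom_spec(0))$autofluorescence,
  45, band_inner = 250, band_outer = 10, step = 10
)

test_that("villous density recovers the exact apex count on a noiseless phantom", {
  dm <- villous_detect(uf_clean)
  expect_identical(dm$total_count, 60L)
  expect_identical(sum(dm$sectors$count), 60L)
})

test_that("villous count is within 10% under 10% amplitude noise", {
  uf_noisy <- unfold_volume(
    make_gut_phantom(villous_phantom_spec(0.088))$autofluorescence,
    45, band_inner = 250, band_outer = 10, step = 10
  )
  dm <- villous_detect(uf_noisy)
  expect_gte(dm$total_count, 54L)
  expect_lte(dm$total_count, 66L)
  expect_identical(sum(dm$sectors$count), dm$total_count)
})

test_that("sector counts always partition the total", {
  dm <- villous_detect(uf_clean)
  expect_identical(sum(dm$sectors$count), dm$total_count)
  expect_equal(
    dm$sectors$density_per_mm2,
    dm$sectors$count / (dm$sector_size * 1e-3)^2
  )
})

test_that("a constant layer yields zero maxima without error", {
  dm <- villous_density(matrix(0.5, 40, 60), 10, 200, min_prominence = 0.05)
  expect_identical(dm$total_count, 0L)
})

test_that("degenerate villous inputs are rejected", {
  expect_error(villous_density(matrix(0.5, 4, 4), 10, 10, 0.1),
    class = "gutopt_parameter_error"
  )
})

test_that("follicle segmentation recovers analytic sphere volumes", {
  fs <- tibble::tibble(
    z_um = 150, y_um = 150, x_um = 150,
    a_um = 100, b_um = 100, c_um = 100, peak = 0.9
  )
  spec <- phantom_spec(
    grid_shape = c(60L, 60L, 60L), voxel_size = 5,
    lumen_radius = 30, mucosa_outer_radius = 50, submucosa_outer_radius = 60,
    muscularis_outer_radius = 70, villus_count_per_ring = 0L, villus_length = 0,
    follicle_specs = fs, noise_sigma = 0, rng_seed = 2L
  )
  ph <- make_gut_phantom(spec)
  # the rendered profile is peak * exp(-2 m^2); the surface m = 1 sits at
  # intensity peak * exp(-2)
  ft <- segment_follicles(ph$marker, 0.9 * exp(-2), smoothing_sigma_um = 2,
                          min_voxels = 10)
  expect_identical(nrow(ft), 1L)
  expect_lt(abs(ft$volume_um3 - 4.18879e6) / 4.18879e6, 0.1)
  expect_equal(ft$volume_um3, ft$voxel_count * 5^3)
  expect_lt(max(abs(c(ft$centroid_z_um, ft$centroid_y_um, ft$centroid_x_um) - 150)), 5)
})

test_that("sphere volume error shrinks as the voxel size decreases", {
  err_at <- function(vox) {
    n <- as.integer(round(300 / vox))
    fs <- tibble::tibble(
      z_um = 150, y_um = 150, x_um = 150,
      a_um = 100, b_um = 100, c_um = 100, peak = 0.9
    )
    spec <- phantom_spec(
      grid_shape = c(n, n, n), voxel_size = vox,
      lumen_radius = 30, mucosa_outer_radius = 50, submucosa_outer_radius = 60,
      muscularis_outer_radius = 70, villus_count_per_ring = 0L,
      villus_length = 0, follicle_specs = fs, noise_sigma = 0, rng_seed = 2L
    )
    ph <- make_gut_phantom(spec)
    ft <- segment_follicles(ph$marker, 0.9 * exp(-2), smoothing_sigma_um = 0,
                            min_voxels = 10)
    abs(ft$volume_um3 - 4 / 3 * pi * 1e6) / (4 / 3 * pi * 1e6)
  }
  errs <- vapply(c(10, 5, 2.5), err_at, numeric(1))
  expect_true(all(diff(errs) <= 1e-9))
})

test_that("the voxel-count filter excludes and includes objects exactly", {
  # two axis-aligned boxes: 27 voxels and 64 voxels, far apart, no smoothing
  arr <- array(0, c(40, 40, 40))
  arr[5:7, 5:7, 5:7] <- 1
  arr[25:28, 25:28, 25:28] <- 1
  vol <- voxel_grid(arr, 5, "marker")
  seg <- function(mv) {
    segment_follicles(vol, 0.5, smoothing_sigma_um = 0, min_voxels = mv)
  }
  expect_identical(seg(1)$voxel_count, c(64L, 27L))
  expect_identical(seg(27)$voxel_count, c(64L, 27L)) # inclusive at the cutoff
  expect_identical(seg(28)$voxel_count, 64L)
  expect_identical(nrow(seg(65)), 0L)
})

test_that("follicle thresholds outside the intensity range are rejected", {
  vol <- voxel_grid(array(runif(1000), c(10, 10, 10)), 5)
  expect_error(segment_follicles(vol, 2), class = "gutopt_parameter_error")
  expect_error(segment_follicles(vol, -0.1), class = "gutopt_parameter_error")
})

test_that("spacing statistics match hand arithmetic for collinear follicles", {
  tab <- tibble::tibble(
    label = 1:3,
    centroid_z_um = c(0, 500, 1000),
    centroid_y_um = 0, centroid_x_um = 0
  )
  fs <- follicle_stats(tab)
  expect_equal(fs$min_distance_um, c(500, 500, 500))
  expect_equal(fs$mean_distance_um, c(750, 500, 750))
  expect_equal(fs$max_distance_um, c(1000, 500, 1000))
})

test_that("spacing statistics equal a brute-force pairwise oracle", {
  set.seed(9)
  n <- 12
  tab <- tibble::tibble(
    label = seq_len(n),
    centroid_z_um = runif(n, 0, 5000),
    centroid_y_um = runif(n, 0, 600),
    centroid_x_um = runif(n, 0, 600)
  )
  fs <- follicle_stats(tab)
  cen <- cbind(tab$centroid_z_um, tab$centroid_y_um, tab$centroid_x_um)
  for (i in seq_len(n)) {
    d <- vapply(
      setdiff(seq_len(n), i),
      function(j) sqrt(sum((cen[i, ] - cen[j, ])^2)),
      numeric(1)
    )
    expect_equal(fs$min_distance_um[i], min(d), tolerance = 1e-12)
    expect_equal(fs$max_distance_um[i], max(d), tolerance = 1e-12)
    expect_equal(fs$mean_distance_um[i], mean(d), tolerance = 1e-12)
  }
})

test_that("degenerate spacing inputs behave as documented", {
  one <- tibble::tibble(label = 1L, centroid_z_um = 0, centroid_y_um = 0,
                        centroid_x_um = 0)
  expect_error(follicle_stats(one), class = "gutopt_insufficient_objects_error")
  twin <- tibble::tibble(
    label = 1:2, centroid_z_um = c(5, 5), centroid_y_um = c(1, 1),
    centroid_x_um = c(2, 2)
  )
  fs <- follicle_stats(twin)
  expect_equal(fs$min_distance_um, c(0, 0))
})

test_that("cell density is the in-mask count over the mask area", {
  s <- make_section_image(400, 1.0, 10, seed = 3)
  expect_equal(cell_density(s$truth$cells, s$nuclei_mask, 10), 400)
  expect_equal(cell_density(s$truth$cells, s$nuclei_mask, 10),
               s$truth$density_per_mm2)

  outside <- tibble::tibble(x_um = c(-50, 1e6), y_um = c(-50, 1e6))
  expect_equal(cell_density(outside, s$nuclei_mask, 10), 0)
  expect_error(cell_density(s$truth$cells, matrix(FALSE, 4, 4), 10),
    class = "gutopt_undefined_density_error"
  )
})

test_that("OPT visibility threshold is inclusive at 400 cells per mm^2", {
  expect_true(opt_visible(400))
  expect_false(opt_visible(399.9))
  expect_false(opt_visible(0))
  expect_true(opt_visible(250, threshold = 250))
  expect_error(opt_visible(-1), class = "gutopt_parameter_error")
})
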
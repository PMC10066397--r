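# Most geometric oracles here use the annulus phantom, whose outline,
# centroid and perimeter are known analytically.

ann <- make_annulus_phantom(80, 120, c(4L, 256L, 256L), 1)
ann_slice <- ann$data[1, , ]

test_that("segmentation recovers the annulus outline and centroid", {
  ol <- segment_tissue(ann_slice, 1)
  expect_lt(max(abs(ol$centroid - 128.5)), 1)
  rad <- sqrt((ol$polygon$x - ol$centroid[["x"]])^2 +
    (ol$polygon$y - ol$centroid[["y"]])^2)
  expect_lt(max(abs(rad - 120)), 2.5)
  expect_lt(abs(mean(rad) - 120), 1)
})

test_that("segmentation keeps only the largest connected component", {
  sl <- matrix(0, 100, 100)
  sl[20:51, 20:51] <- 1 # ~1000 px after the checks below
  sl[80:86, 80:86] <- 1 # ~50 px
  ol <- segment_tissue(sl)
  expect_true(ol$centroid[["x"]] < 60 && ol$centroid[["y"]] < 60)
  expect_true(all(ol$polygon$x < 60))
})

test_that("slices without foreground raise an empty-mask error", {
  expect_error(segment_tissue(matrix(0, 32, 32)), class = "gutopt_empty_mask_error")
})

test_that("the seam lands on the requested angular position", {
  # circle of radius 100 centred near (200, 200) in a 400 x 400 image
  sl <- disk_slice(400, 100)
  ol <- segment_tissue(sl)
  ol45 <- compute_seam(ol, 45)
  seam <- ol45$polygon[ol45$seam_vertex, ]
  cx <- ol$centroid[["x"]]
  cy <- ol$centroid[["y"]]
  # y-down convention: +45 degrees is up and to the right
  expect_lt(abs(seam$x - (cx + 100 * cos(pi / 4))), 1.5)
  expect_lt(abs(seam$y - (cy - 100 * sin(pi / 4))), 1.5)

  ol0 <- compute_seam(ol, 0)
  seam0 <- ol0$polygon[ol0$seam_vertex, ]
  expect_lt(abs(seam0$x - (cx + 100)), 1.5)
  expect_lt(abs(seam0$y - cy), 1.5)

  # periodicity
  expect_identical(compute_seam(ol, 405)$seam_vertex, ol45$seam_vertex)
})

test_that("straightening an annulus matches the analytic perimeter and is uniform", {
  ol <- compute_seam(segment_tissue(ann_slice, 1), 45)
  st <- straighten_slice(ann_slice, ol, band_inner = 50, band_outer = 10,
                         step = 1, pixel_size = 1)
  expected <- 2 * pi * 120
  expect_lt(abs(ncol(st) - expected) / expected, 0.02)
  expect_lt(abs(attr(st, "perimeter_um") - expected) / expected, 0.02)

  # interior band rows are constant along arc length
  depth <- attr(st, "depth_um")
  band <- st[depth >= 15 & depth <= 35, , drop = FALSE]
  cv <- apply(band, 2, stats::sd) / colMeans(band)
  expect_lt(max(cv), 0.01)
})

test_that("straightening preserves the sampled band mass for a thin band", {
  ol <- compute_seam(segment_tissue(ann_slice, 1), 45)
  st <- straighten_slice(ann_slice, ol, band_inner = 4, band_outer = 0,
                         step = 1, pixel_size = 1)
  # band-masked slice mass: the 5 sampled depth rows cover a shell of about
  # 5 px thickness at the outer rim
  c0 <- 128.5
  g <- expand.grid(y = 1:256, x = 1:256)
  r <- matrix(sqrt((g$y - c0)^2 + (g$x - c0)^2), 256, 256)
  band_mask <- r <= 120 & r > 115
  expect_lt(abs(sum(st) - sum(ann_slice[band_mask])) / sum(ann_slice[band_mask]), 0.05)
})

test_that("straightening is equivariant under joint slice and seam rotation", {
  # short axial period puts a full villus ring on slice 1, so the slice has
  # angular structure for the equivariance check
  spec <- phantom_spec(
    grid_shape = c(2L, 80L, 80L), noise_sigma = 0,
    villus_axial_period = 10, follicle_specs = empty_follicles()
  )
  sl <- make_gut_phantom(spec)$autofluorescence$data[1, , ]
  # soften the knife-edge layer boundaries (as in reconstructed data) so the
  # comparison measures geometry, not edge aliasing of the test's rotation
  sl <- gutopt:::gauss_blur_3d(array(sl, c(1, dim(sl))), 1)[1, , ]
  straighten_at <- function(img, seam_angle) {
    ol <- compute_seam(segment_tissue(img), seam_angle)
    straighten_slice(img, ol, band_inner = 200, band_outer = 10,
                     step = 10, pixel_size = 10)
  }
  base <- straighten_at(sl, 45)
  rot <- straighten_at(gutopt:::rotate_image(sl, 30), 75)
  w <- min(ncol(base), ncol(rot)) - 2L
  dyn <- diff(range(base))
  # the seam vertex is quantised to outline pixels, so allow a +-1 column
  # arc shift when comparing
  err_at_lag <- vapply(-1:1, function(lag) {
    cols <- 2:w
    mean(abs(base[, cols] - rot[, cols + lag]))
  }, numeric(1))
  expect_lt(min(err_at_lag), 0.05 * dyn)
})

test_that("band depths beyond the centroid distance warn and clamp", {
  ol <- compute_seam(segment_tissue(ann_slice, 1), 45)
  expect_warning(
    straighten_slice(ann_slice, ol, band_inner = 200, band_outer = 0,
                     step = 1, pixel_size = 1),
    class = "gutopt_geometry_warning"
  )
})

test_that("unfolding produces an exact orthogonal reslice of the straightened stack", {
  uf <- unfold_volume(ann, 45, band_inner = 50, band_outer = 10, step = 1)
  expect_identical(uf$unfolded_volume, aperm(uf$straightened_stack, c(2, 1, 3)))
  expect_identical(
    sort(as.vector(uf$unfolded_volume)),
    sort(as.vector(uf$straightened_stack))
  )
  # layers inside the annulus band are uniform; outside they are empty
  li <- unfolded_layer(uf, 25)
  expect_lt(stats::sd(as.vector(li)), 1e-12)
  expect_gt(mean(li), 0.99)
  expect_lt(max(unfolded_layer(uf, -8)), 1e-12)
})

test_that("seam points are collinear across slices of a straight cylinder", {
  uf <- unfold_volume(ann, 45, band_inner = 30, band_outer = 5, step = 1)
  expect_lt(diff(range(uf$seams$seam_x)), 1 + 1e-9)
  expect_lt(diff(range(uf$seams$seam_y)), 1 + 1e-9)
})

test_that("single-slice volumes unfold to layers of height one", {
  one <- make_annulus_phantom(80, 120, c(1L, 256L, 256L), 1)
  uf <- unfold_volume(one, 45, band_inner = 30, band_outer = 5, step = 1)
  expect_identical(dim(uf$unfolded_volume)[2], 1L)
})

test_that("slice failures are tolerated up to 20% and abort beyond", {
  # 1 of 5 slices empty: proceeds with zero fill
  vol_ok <- make_annulus_phantom(80, 120, c(5L, 256L, 256L), 1)
  vol_ok$data[3, , ] <- 0
  uf <- unfold_volume(vol_ok, 45, band_inner = 30, band_outer = 5, step = 1)
  expect_identical(sum(!uf$seams$ok), 1L)
  expect_identical(max(abs(uf$straightened_stack[3, , ])), 0)

  # 2 of 5 slices empty (40%): aborts with the slice indices
  vol_bad <- make_annulus_phantom(80, 120, c(5L, 256L, 256L), 1)
  vol_bad$data[2, , ] <- 0
  vol_bad$data[4, , ] <- 0
  expect_error(
    unfold_volume(vol_bad, 45, band_inner = 30, band_outer = 5, step = 1),
    class = "gutopt_empty_mask_error"
  )
})
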
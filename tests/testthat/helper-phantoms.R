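# Shared fixture builders; everything is generated in code at test time.

empty_follicles <- function() {
  tibble::tibble(
    z_um = numeric(), y_um = numeric(), x_um = numeric(),
    a_um = numeric(), b_um = numeric(), c_um = numeric(), peak = numeric()
  )
}

# Small villous phantom: 80 slices at 10 um (800 um), 160 um ring period and
# 12 villi per ring -> exactly 5 * 12 = 60 villus apexes.
villous_phantom_spec <- function(noise_sigma = 0) {
  phantom_spec(
    grid_shape = c(80L, 80L, 80L),
    voxel_size = 10,
    noise_sigma = noise_sigma,
    follicle_specs = empty_follicles(),
    rng_seed = 11L
  )
}

# Canonical villous detection settings for the phantom above: detect on the
# mid-villus layer; scales are in unfolded arc units (stretched by
# r_outline / r_layer relative to physical villus width).
villous_detect <- function(uf) {
  layer <- unfolded_layer(uf, 300 - (150 - 60 / 2))
  villous_density(
    layer,
    pixel_size = 10, sector_size = 200,
    min_prominence = 0.15, sigma_um = 30, min_separation_um = 90
  )
}

# Uniform disk slice (value 1) of radius r_px in an n x n matrix.
disk_slice <- function(n, r_px, value = 1) {
  c0 <- (n + 1) / 2
  g <- expand.grid(y = seq_len(n), x = seq_len(n))
  m <- matrix(0, n, n)
  m[matrix(sqrt((g$y - c0)^2 + (g$x - c0)^2) <= r_px, n, n)] <- value
  m
}

# Two-layer disk phantom used for reconstruction round trips.
two_layer_disk <- function(n = 128, nz = 2, r_outer = 40, r_inner = 20,
                           voxel = 10) {
  sl <- disk_slice(n, r_outer, 1)
  sl[disk_slice(n, r_inner) > 0] <- 0.5
  arr <- array(0, c(nz, n, n))
  for (k in seq_len(nz)) arr[k, , ] <- sl
  voxel_grid(arr, voxel, "disk")
}

# Exact 90 degree rotation of a square matrix about its centre
# (counterclockwise in the y-down image convention, matching
# gutopt:::rotate_image(m, 90)): out[i, j] = m[j, n + 1 - i].
rot90_exact <- function(m) {
  n <- nrow(m)
  t(m)[n:1, , drop = FALSE]
}
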
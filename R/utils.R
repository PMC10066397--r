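# Internal numeric helpers shared across modules.

next_pow2 <- function(n) {
  2L^as.integer(ceiling(log2(max(2, n))))
}

# Vectorised bilinear interpolation of a matrix at fractional (row, col)
# coordinates. Coordinates are 1-based; points outside the image sample 0.
bilinear_sample <- function(img, row, col) {
  nr <- nrow(img)
  nc <- ncol(img)
  r0 <- floor(row)
  c0 <- floor(col)
  fr <- row - r0
  fc <- col - c0

  val <- numeric(length(row))
  # contributions of the four surrounding pixels
  for (dr in 0:1) {
    for (dc in 0:1) {
      rr <- r0 + dr
      cc <- c0 + dc
      w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
      ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc & w > 0
      if (any(ok)) {
        val[ok] <- val[ok] + w[ok] * img[cbind(rr[ok], cc[ok])]
      }
    }
  }
  val
}

# Rotate image content by `angle_deg` (counterclockwise from the +x axis in
# the y-down image convention) about the image centre, bilinear, zero fill.
rotate_image <- function(img, angle_deg) {
  nr <- nrow(img)
  nc <- ncol(img)
  cy <- (nr + 1) / 2
  cx <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  g <- expand.grid(row = seq_len(nr), col = seq_len(nc))
  yc <- g$row - cy
  xc <- g$col - cx
  # inverse mapping: target angle phi corresponds to source angle phi - th,
  # with phi measured counterclockwise in the y-down convention
  src_x <- cx + xc * cos(th) - yc * sin(th)
  src_y <- cy + xc * sin(th) + yc * cos(th)
  matrix(bilinear_sample(img, src_y, src_x), nr, nc)
}

# Separable Gaussian smoothing of a 3D array, sigma in voxels (scalar).
gauss_blur_3d <- function(a, sigma_vox) {
  if (sigma_vox <= 0.15) {
    return(a)
  }
  h <- max(1L, as.integer(ceiling(3 * sigma_vox)))
  k <- exp(-((-h:h)^2) / (2 * sigma_vox^2))
  k <- k / sum(k)
  d <- dim(a)
  for (ax in 1:3) {
    perm <- c(ax, setdiff(1:3, ax))
    m <- matrix(aperm(a, perm), d[ax])
    m <- conv_cols_reflect(m, k)
    a <- aperm(array(m, d[perm]), order(perm))
  }
  a
}

# Convolve each column of `m` with kernel `k` (odd length), reflecting at
# the boundaries.
conv_cols_reflect <- function(m, k) {
  h <- (length(k) - 1L) / 2L
  n <- nrow(m)
  idx <- seq_len(n)
  out <- matrix(0, n, ncol(m))
  for (j in seq_along(k)) {
    src <- idx + (j - h - 1L)
    src[src < 1L] <- 2L - src[src < 1L]
    src[src > n] <- 2L * n - src[src > n]
    src <- pmin(pmax(src, 1L), n) # short axes: clamp after one reflection
    out <- out + k[j] * m[src, , drop = FALSE]
  }
  out
}

# 26-connected component labelling of a logical 3D array. Returns an integer
# array of labels (0 = background). Edges between foreground voxels are
# enumerated by vectorised array shifts and components come from igraph.
label_components_3d <- function(bw) {
  d <- dim(bw)
  stopifnot(length(d) == 3L)
  idx <- which(bw)
  lab <- array(0L, d)
  if (length(idx) == 0L) {
    return(lab)
  }
  rank <- array(0L, d)
  rank[idx] <- seq_along(idx)

  offsets <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  offsets <- offsets[offsets[, 1] != 0 | offsets[, 2] != 0 | offsets[, 3] != 0, ]
  # keep one of each +/- pair
  keep <- apply(offsets, 1, function(o) {
    o[1] > 0 || (o[1] == 0 && (o[2] > 0 || (o[2] == 0 && o[3] > 0)))
  })
  offsets <- offsets[keep, , drop = FALSE]

  rng <- function(n, o) if (o >= 0) seq_len(n - o) else seq(1 - o, n)
  edges <- vector("list", nrow(offsets))
  for (i in seq_len(nrow(offsets))) {
    o <- offsets[i, ]
    a <- rank[rng(d[1], o[1]), rng(d[2], o[2]), rng(d[3], o[3]), drop = FALSE]
    b <- rank[rng(d[1], -o[1]), rng(d[2], -o[2]), rng(d[3], -o[3]), drop = FALSE]
    sel <- a > 0L & b > 0L
    edges[[i]] <- cbind(a[sel], b[sel])
  }
  edges <- do.call(rbind, edges)

  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges) && nrow(edges) > 0) {
    g <- igraph::add_edges(g, t(edges))
  }
  comp <- igraph::components(g)
  lab[idx] <- comp$membership
  lab
}

# Normalised cross-correlation between two equally shaped numeric arrays,
# optionally restricted to a logical mask.
ncc <- function(a, b, mask = NULL) {
  if (!is.null(mask)) {
    a <- a[mask]
    b <- b[mask]
  }
  a <- a - mean(a)
  b <- b - mean(b)
  sum(a * b) / sqrt(sum(a^2) * sum(b^2))
}

stop_geometry <- function(msg) {
  abort(msg, class = "gutopt_geometry_error")
}

stop_parameter <- function(msg) {
  abort(msg, class = "gutopt_parameter_error")
}
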
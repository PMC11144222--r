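# Shared fixtures, built in code at test time.

# phantom with a single isolated cubic tooth (edge voxels), soft-tissue
# background; convenient for deformation oracles
cubic_tooth_phantom <- function(n = 32, edge = 10, pitch = 1) {
  labels <- array(8L, dim = c(n, n, n))
  lo <- (n - edge) %/% 2 + 1
  hi <- lo + edge - 1
  labels[lo:hi, lo:hi, lo:hi] <- 10L
  instances <- array(0L, dim = c(n, n, n))
  instances[lo:hi, lo:hi, lo:hi] <- 101L
  voxel_phantom(labels, instances, pitch = pitch)
}

# homogeneous axis-aligned cuboid of one material in air
block_phantom <- function(n = 64, extent = 32, label = 8L, pitch = 1) {
  labels <- array(0L, dim = c(n, n, n))
  lo <- (n - extent) %/% 2 + 1
  hi <- lo + extent - 1
  labels[lo:hi, lo:hi, lo:hi] <- label
  voxel_phantom(labels, pitch = pitch)
}

# centered homogeneous cylinder along z (radius in voxels)
cylinder_phantom <- function(n = 96, nz = 32, radius = 20, label = 8L,
                             pitch = 1) {
  labels <- array(0L, dim = c(n, n, nz))
  cc <- seq_len(n) - (n + 1) / 2
  disk <- outer(cc^2, cc^2, `+`) <= radius^2
  for (k in seq_len(nz)) {
    slice <- labels[, , k]
    slice[disk] <- label
    labels[, , k] <- slice
  }
  voxel_phantom(labels, pitch = pitch)
}

# small scan geometry for desk-scale simulations
test_geometry <- function(cols = 96, rows = 64, pitch = 1.2,
                          n_proj = 60) {
  scan_geometry(detector_cols = cols, detector_rows = rows,
                detector_pitch = pitch, n_projections = n_proj,
                angular_step = 360 / n_proj)
}

# synthetic ellipsoid tooth sample for segmentation tests
ellipsoid_sample <- function(seed, size = 32) {
  set.seed(seed)
  cx <- stats::runif(3, size * 0.35, size * 0.65)
  r <- stats::runif(3, size * 0.12, size * 0.25)
  g <- expand.grid(x = seq_len(size), y = seq_len(size), z = seq_len(size))
  d <- ((g$x - cx[1]) / r[1])^2 + ((g$y - cx[2]) / r[2])^2 +
    ((g$z - cx[3]) / r[3])^2
  mask <- array(as.integer(d <= 1), rep(size, 3))
  img <- array(stats::rnorm(size^3, 0.1, 0.03), rep(size, 3)) + 0.4 * mask
  vcbct:::tooth_sample(img, mask, meta = list(tooth_id = 101L))
}

# independent slab-clipping oracle for ray/box chord length (cm)
box_chord_oracle <- function(s, e, lo, hi) {
  d <- e - s
  amin <- 0
  amax <- 1
  for (ax in 1:3) {
    if (abs(d[ax]) < 1e-14) {
      if (s[ax] < lo[ax] || s[ax] > hi[ax]) return(0)
    } else {
      a1 <- (lo[ax] - s[ax]) / d[ax]
      a2 <- (hi[ax] - s[ax]) / d[ax]
      amin <- max(amin, min(a1, a2))
      amax <- min(amax, max(a1, a2))
    }
  }
  if (amin >= amax) return(0)
  (amax - amin) * sqrt(sum(d^2))
}

# source/pixel positions mirroring the package's geometry conventions
ray_endpoints <- function(geometry, angle, pixel) {
  b <- angle * pi / 180
  sid <- geometry$source_to_isocenter
  sdd <- geometry$source_to_detector
  du <- geometry$detector_pitch / 10
  s <- c(sid * cos(b), sid * sin(b), 0)
  u <- (pixel[1] - (geometry$detector_cols + 1) / 2) * du
  v <- (pixel[2] - (geometry$detector_rows + 1) / 2) * du
  e <- c(s[1] - sdd * cos(b) - u * sin(b),
         s[2] - sdd * sin(b) + u * cos(b),
         v)
  list(s = s, e = e)
}
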
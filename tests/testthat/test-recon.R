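test_that("ramp window is zero at DC, even, and cut off at W Nyquist", {
  spec <- filter_spec(alpha = 0.54, gamma = 1.0, W = 0.8)
  expect_equal(ramp_window(0, spec), 0)
  nu <- seq(-0.5, 0.5, by = 0.05)
  expect_equal(ramp_window(nu, spec), ramp_window(-nu, spec))
  # 0.45 cycles/sample lies beyond W * Nyquist = 0.4
  expect_equal(ramp_window(0.45, spec), 0)
  expect_equal(ramp_window(0.5, spec), 0)
  # inside the passband: |v| times the generalized-Hamming window
  v <- 0.25
  expect_equal(ramp_window(v, spec),
               v * (0.54 + 0.46 * cos(pi * v / 0.5)))
  expect_true(all(ramp_window(nu, spec) >= 0))
})

test_that("filter parameters are validated", {
  expect_error(filter_spec(alpha = 0), "alpha")
  expect_error(filter_spec(gamma = -1), "gamma")
  expect_error(filter_spec(W = 1.2), "W")
})

test_that("FDK recovers the attenuation of a homogeneous cylinder", {
  ph <- cylinder_phantom(n = 96, nz = 32, radius = 20, label = 8L, pitch = 1)
  geom <- test_geometry(cols = 128, rows = 48, pitch = 1.2, n_proj = 90)
  sp <- load_spectrum("mono-60")
  stack <- forward_project(ph, sp, geom)
  vol <- fdk_reconstruct(stack, out_dim = c(64, 64, 16), pitch = 1)
  mu <- mu_material(8, 60)
  cc <- seq_len(64) - 32.5
  inner <- outer(cc^2, cc^2, `+`) <= 10^2   # central 50% of the radius
  mid <- vol$values[, , 8]
  expect_equal(mean(mid[inner]), mu, tolerance = 0.1)
  # radial profile flat to +/- 10% inside half radius
  expect_lt(max(abs(mid[inner] - mu)) / mu, 0.12)

  # an empty scan reconstructs to (almost) nothing
  empty <- stack
  empty$ratios[] <- 1
  vol0 <- fdk_reconstruct(empty, out_dim = c(64, 64, 16), pitch = 1)
  expect_lt(max(abs(vol0$values)), 0.01 * mu)
})

test_that("reconstruction is linear in density for monoenergetic scans", {
  ph1 <- cylinder_phantom(n = 64, nz = 24, radius = 14, label = 8L,
                          pitch = 1)
  ph2 <- vary_densities(ph1, c("8" = 2))
  geom <- test_geometry(cols = 96, rows = 32, pitch = 1.2, n_proj = 72)
  sp <- load_spectrum("mono-60")
  grab_mean <- function(ph) {
    vol <- fdk_reconstruct(forward_project(ph, sp, geom),
                           out_dim = c(48, 48, 12), pitch = 1)
    cc <- seq_len(48) - 24.5
    inner <- outer(cc^2, cc^2, `+`) <= 7^2
    mean(vol$values[, , 6][inner])
  }
  expect_equal(grab_mean(ph2) / grab_mean(ph1), 2, tolerance = 0.05)
})

test_that("more views reduce the error against the attenuation map", {
  ph <- cylinder_phantom(n = 64, nz = 24, radius = 14, label = 8L, pitch = 1)
  sp <- load_spectrum("mono-60")
  mu <- mu_material(8, 60)
  cc <- seq_len(48) - 24.5
  inner <- outer(cc^2, cc^2, `+`) <= 12^2
  rms <- vapply(c(45, 90), function(nv) {
    geom <- test_geometry(cols = 96, rows = 32, pitch = 1.2, n_proj = nv)
    vol <- fdk_reconstruct(forward_project(ph, sp, geom),
                           out_dim = c(48, 48, 12), pitch = 1)
    truth <- ifelse(inner, mu, 0)
    sqrt(mean((vol$values[, , 6] - truth)^2))
  }, numeric(1))
  expect_lt(rms[2], rms[1])
})

test_that("FDK rejects partial scans", {
  ph <- block_phantom(n = 16, extent = 8, pitch = 1)
  geom <- scan_geometry(detector_cols = 16, detector_rows = 8,
                        detector_pitch = 2, n_projections = 10,
                        angular_step = 10)
  stack <- forward_project(ph, load_spectrum("mono-60"), geom)
  expect_error(fdk_reconstruct(stack), "360")
})

test_that("median filter removes impulses and preserves constants", {
  const <- array(3.5, c(8, 8, 4))
  expect_equal(median_filter_3x3(const), const)

  imp <- const
  imp[4, 4, 2] <- 100
  out <- median_filter_3x3(imp)
  expect_equal(out, const)

  # bounded by the slice range
  set.seed(3)
  noisy <- array(rnorm(8 * 8 * 4), c(8, 8, 4))
  filt <- median_filter_3x3(noisy)
  for (k in 1:4) {
    expect_gte(min(filt[, , k]), min(noisy[, , k]))
    expect_lte(max(filt[, , k]), max(noisy[, , k]))
  }
})

test_that("slice-median matches a brute-force sort oracle", {
  set.seed(11)
  slice <- matrix(sample(1:100, 25), 5, 5)
  vol <- array(slice, c(5, 5, 1))
  out <- median_filter_3x3(vol)[, , 1]
  pad <- rbind(slice[1, ], slice, slice[5, ])
  pad <- cbind(pad[, 1], pad, pad[, 5])
  for (i in 1:5) for (j in 1:5) {
    nb <- as.vector(pad[i:(i + 2), j:(j + 2)])
    expect_equal(out[i, j], sort(nb)[5])
  }
})

test_that("median filtering is idempotent on piecewise-constant volumes", {
  vol <- array(0, c(12, 12, 3))
  vol[1:6, , ] <- 1
  once <- median_filter_3x3(vol)
  twice <- median_filter_3x3(once)
  expect_equal(twice, once)
})

test_that("reconstructed volumes round-trip through disk", {
  vol <- vcbct:::recon_volume(array(rnorm(4^3), c(4, 4, 4)), pitch = 0.5,
                              provenance = list(note = "test"))
  path <- file.path(withr::local_tempdir(), "vol.nii.gz")
  write_recon_volume(vol, path)
  back <- read_recon_volume(path)
  expect_equal(back$values, vol$values, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(back$voxel_pitch, vol$voxel_pitch)
})
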
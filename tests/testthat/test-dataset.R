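test_that("condition enumeration is the ordered Cartesian product", {
  grid <- condition_grid()
  conds <- enumerate_conditions(grid)
  expect_equal(nrow(conds), 7 * 2 * 3 * 3 * 1)

  one <- condition_grid(phantoms = 1, density_sets = 1, spectra = "mono-60",
                        noise_levels = list("none"), cutoffs = list("none"),
                        augmentations = 1)
  expect_equal(nrow(enumerate_conditions(one)), 1)

  small <- condition_grid(phantoms = 2, density_sets = 1,
                          spectra = "mono-60",
                          noise_levels = list("none", 1e4),
                          cutoffs = list(0.004, 0.016), augmentations = 1)
  conds <- enumerate_conditions(small)
  expect_equal(nrow(conds), 8)
  # documented order: cutoff fastest, phantom slowest
  expect_equal(conds$cutoff[1:2], c("0.004", "0.016"))
  expect_equal(conds$phantom[1:4], rep("phantom1", 4))
  # deterministic
  expect_identical(conds, enumerate_conditions(small))
})

test_that("the default grid with 27 teeth yields the full corpus size", {
  expect_equal(count_samples(condition_grid(), teeth_per_phantom = 27),
               170100)
  # alternative factorization: two cutoffs, 25 augmentations
  alt <- condition_grid(cutoffs = list(0.004, 0.016), augmentations = 25)
  expect_equal(count_samples(alt, teeth_per_phantom = 27), 170100)
  # degenerate grid
  one <- condition_grid(phantoms = 1, density_sets = 1, spectra = "mono-60",
                        noise_levels = list("none"), cutoffs = list("none"),
                        augmentations = 1)
  expect_equal(count_samples(one, teeth_per_phantom = 1), 1)
})

test_that("tooth crops have the requested size and seeded margins", {
  ph <- build_synthetic_jaw(size = 48, n_teeth = 2, seed = 1, pitch = 1)
  geom <- test_geometry(cols = 80, rows = 64, pitch = 1.2, n_proj = 45)
  stack <- forward_project(ph, load_spectrum("mono-60"), geom)
  vol <- fdk_reconstruct(stack, out_dim = c(48, 48, 48), pitch = 1)

  s <- crop_tooth(vol, ph, 101, margin_range = c(2, 4), out_size = 32,
                  seed = 7)
  expect_equal(dim(s$image), c(32, 32, 32))
  expect_equal(dim(s$mask), c(32, 32, 32))
  expect_gt(sum(s$mask), 0)
  expect_equal(s$meta$tooth_id, 101L)

  s2 <- crop_tooth(vol, ph, 101, margin_range = c(2, 4), out_size = 32,
                   seed = 7)
  expect_identical(s$meta$margins, s2$meta$margins)
  expect_identical(s$image, s2$image)

  # the mask excludes the other tooth even if it enters the crop box
  other <- crop_tooth(vol, ph, 102, margin_range = c(2, 4), out_size = 32,
                      seed = 7)
  expect_gt(sum(other$mask), 0)
  expect_error(crop_tooth(vol, ph, 115, out_size = 32), "not present")

  # teeth reconstruct brighter than their surroundings
  expect_gt(mean(s$image[s$mask == 1]), mean(s$image[s$mask == 0]))
})

test_that("zero margins give a tight bounding box crop", {
  ph <- cubic_tooth_phantom(n = 32, edge = 8, pitch = 1)
  vol <- vcbct:::recon_volume(array(as.numeric(ph$labels == 10L),
                                    dim = dim(ph$labels)), pitch = 1)
  s <- crop_tooth(vol, ph, 101, margin_range = c(0, 0), out_size = 16,
                  seed = 1)
  # the cubic tooth fills the whole resampled crop
  expect_true(all(s$mask == 1))
})

test_that("the 48 orientation transforms are distinct and involutive", {
  trs <- orientation_transforms()
  expect_equal(length(trs), 48)
  expect_equal(trs[[1]]$perm, 1:3)
  expect_false(any(trs[[1]]$flips))

  set.seed(5)
  asym <- array(stats::rnorm(4^3), c(4, 4, 4))
  images <- lapply(trs, function(tr) apply_orientation(asym, tr))
  keys <- vapply(images, function(a) paste(signif(a, 12), collapse = ","),
                 "")
  expect_equal(length(unique(keys)), 48)

  # a pure flip is an involution
  flip <- list(perm = 1:3, flips = c(TRUE, FALSE, TRUE))
  expect_equal(apply_orientation(apply_orientation(asym, flip), flip), asym)
})

test_that("orientation augmentation is seeded and identity-first", {
  s <- ellipsoid_sample(3)
  out <- augment_orientations(s, 1, seed = 9)
  expect_identical(out[[1]]$image, s$image)

  a <- augment_orientations(s, 5, seed = 9)
  b <- augment_orientations(s, 5, seed = 9)
  for (i in 1:5) expect_identical(a[[i]]$image, b[[i]]$image)

  all48 <- augment_orientations(s, 48, seed = 9)
  keys <- vapply(all48, function(x) {
    paste(x$meta$orientation, paste(as.integer(x$meta$flips), collapse = ""),
          collapse = "")
  }, "")
  expect_equal(length(unique(keys)), 48)
  expect_error(augment_orientations(s, 49), "48")

  # voxel-value multisets are invariant under orientation transforms
  for (x in a) {
    expect_equal(sort(as.vector(x$image)), sort(as.vector(s$image)))
    expect_equal(sum(x$mask), sum(s$mask))
  }
})

test_that("generated corpora match the combinatorial count and resume", {
  ph <- build_synthetic_jaw(size = 40, n_teeth = 2, seed = 2, pitch = 1)
  grid <- condition_grid(
    phantoms = list(base = ph), density_sets = list(ref = NULL),
    spectra = "mono-60", noise_levels = list("none", 1e5),
    cutoffs = list("none"), augmentations = 3)
  dir <- withr::local_tempdir()
  geom <- test_geometry(cols = 64, rows = 48, pitch = 1.4, n_proj = 40)
  man <- generate_dataset(grid, dir, seed = 4, geometry = geom,
                          recon_dim = c(40, 40, 40), recon_pitch = 1,
                          out_size = 32, margin_range = c(2, 4))
  expect_equal(nrow(man), count_samples(grid, teeth_per_phantom = 2))
  expect_true(all(man$status == "ok"))

  # every sample loads, has a nonempty mask and matching shapes
  for (i in seq_len(nrow(man))) {
    s <- read_tooth_sample(file.path(dir, man$file[i]))
    expect_equal(dim(s$image), dim(s$mask))
    expect_gt(sum(s$mask), 0)
  }

  # re-running is a no-op
  man2 <- generate_dataset(grid, dir, seed = 4, geometry = geom,
                           recon_dim = c(40, 40, 40), recon_pitch = 1,
                           out_size = 32, margin_range = c(2, 4))
  expect_equal(nrow(man2), nrow(man))

  # regeneration from scratch with the same seed is bit-identical
  dir2 <- withr::local_tempdir()
  generate_dataset(grid, dir2, seed = 4, geometry = geom,
                   recon_dim = c(40, 40, 40), recon_pitch = 1,
                   out_size = 32, margin_range = c(2, 4))
  s1 <- read_tooth_sample(file.path(dir, man$file[3]))
  s2 <- read_tooth_sample(file.path(dir2, man$file[3]))
  expect_identical(s1$image, s2$image)
  expect_identical(s1$mask, s2$mask)
})
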
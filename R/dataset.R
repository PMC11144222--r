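#' Define a phantom-by-scan-condition grid
#'
#' Describes the Cartesian grid of imaging conditions from which the
#' per-tooth training corpus is generated: phantom variants x density sets
#' x spectra x noise levels x cutoffs, with an orientation/crop augmentation
#' count per tooth.  The defaults reproduce the reference corpus layout:
#' 7 phantoms, 2 density sets, 3 spectra, 3 noise levels (none, 1e4, 1e5),
#' a single cutoff setting and 50 augmentations, which with 27 teeth per
#' phantom gives 170,100 samples.
#'
#' For counting and enumeration, `phantoms` and `density_sets` may be bare
#' counts; for [generate_dataset()] they must be a list of `voxel_phantom`
#' objects and a list of density-multiplier maps (an entry of `NULL` means
#' the unmodified table).
#'
#' @param phantoms integer count, or named list of `voxel_phantom`s.
#' @param density_sets integer count, or named list of per-structure density
#'   multiplier maps as accepted by [vary_densities()] (`NULL` entries =
#'   reference densities).
#' @param spectra character vector of spectrum names for [load_spectrum()].
#' @param noise_levels list of incident photon counts, with `"none"` for a
#'   noise-free scan.
#' @param cutoffs list of cutoff ratios, with `"none"` for no cutoff.
#' @param augmentations samples generated per tooth and condition (>= 1);
#'   the first 48 use distinct orientation transforms, further ones redraw
#'   the crop margins.
#' @return A `condition_grid`.
#' @export
condition_grid <- function(phantoms = 7, density_sets = 2,
                           spectra = c("soft-90kVp", "hard-90kVp", "100kVp"),
                           noise_levels = list("none", 1e4, 1e5),
                           cutoffs = list("none"),
                           augmentations = 50) {
  counts <- c(
    P = if (is.list(phantoms)) length(phantoms) else as.integer(phantoms),
    D = if (is.list(density_sets)) length(density_sets)
        else as.integer(density_sets),
    S = length(spectra), N = length(noise_levels), C = length(cutoffs)
  )
  if (any(counts < 1) || augmentations < 1) {
    stop("all condition counts and the augmentation count must be >= 1")
  }
  structure(list(phantoms = phantoms, density_sets = density_sets,
                 spectra = spectra, noise_levels = noise_levels,
                 cutoffs = cutoffs,
                 augmentations = as.integer(augmentations),
                 counts = counts),
            class = "condition_grid")
}

grid_names <- function(x, prefix) {
  if (is.list(x)) {
    nm <- names(x)
    if (is.null(nm)) nm <- rep("", length(x))
    empty <- !nzchar(nm)
    nm[empty] <- paste0(prefix, which(empty))
    nm
  } else {
    paste0(prefix, seq_len(x))
  }
}

#' Enumerate the conditions of a grid
#'
#' Expands the Cartesian product in a fixed documented order: the cutoff
#' index varies fastest, then noise, spectrum, density set, and phantom
#' slowest.
#'
#' @param grid a `condition_grid`.
#' @return A data frame with one row per condition: `condition` (1-based
#'   index), `phantom`, `density_set`, `spectrum`, `noise`, `cutoff`.
#' @export
enumerate_conditions <- function(grid) {
  noise_lab <- vapply(grid$noise_levels, function(x) {
    if (identical(x, "none")) "none" else format(x, scientific = TRUE)
  }, "")
  cut_lab <- vapply(grid$cutoffs, function(x) {
    if (identical(x, "none")) "none" else format(x)
  }, "")
  out <- expand.grid(
    cutoff = cut_lab, noise = noise_lab, spectrum = grid$spectra,
    density_set = grid_names(grid$density_sets, "density"),
    phantom = grid_names(grid$phantoms, "phantom"),
    stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE
  )
  out <- out[, c("phantom", "density_set", "spectrum", "noise", "cutoff")]
  data.frame(condition = seq_len(nrow(out)), out)
}

#' Count the samples a grid will generate
#'
#' The product P x D x S x N x C x teeth x augmentations, computed without
#' generating any data.
#'
#' @param grid a `condition_grid`.
#' @param teeth_per_phantom number of teeth in each phantom (the reference
#'   head phantom has 27: 12 upper, 15 lower).
#' @return Integer sample count.
#' @export
#' @examples
#' count_samples(condition_grid(), teeth_per_phantom = 27)  # 170100
count_samples <- function(grid, teeth_per_phantom) {
  prod(grid$counts) * teeth_per_phantom * grid$augmentations
}

#' Crop one tooth from a reconstructed volume
#'
#' Takes the bounding box of the tooth's instance mask, expands each face by
#' an integer margin drawn uniformly from `margin_range` (seeded), and
#' resamples the box to `out_size^3`: trilinearly for the image, nearest-
#' neighbour for the mask.  The mask contains only the requested tooth.
#' The reconstruction and the phantom share the isocenter-centered frame,
#' so their grids may differ in size and pitch.
#'
#' @param vol a `recon_volume`.
#' @param phantom the `voxel_phantom` that was scanned.
#' @param tooth_id anatomical tooth ID present in the phantom.
#' @param margin_range integer range (min, max) of the per-face margin, in
#'   phantom voxels.
#' @param out_size output cube edge, voxels (reference protocol: 128).
#' @param seed integer seed for the margin draws.
#' @return A `tooth_sample`: list with `image` and `mask` arrays of
#'   dimension `out_size^3` and a `meta` provenance list.
#' @export
crop_tooth <- function(vol, phantom, tooth_id, margin_range = c(2, 10),
                       out_size = 128, seed = NULL) {
  mask <- phantom$tooth_instances == as.integer(tooth_id)
  if (!any(mask)) stop("tooth ", tooth_id, " not present in phantom")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  idx <- which(mask, arr.ind = TRUE)
  lo <- apply(idx, 2, min)
  hi <- apply(idx, 2, max)
  margins <- sample(margin_range[1]:margin_range[2], 6, replace = TRUE)
  lo <- lo - margins[1:3]
  hi <- hi + margins[4:6]
  pd <- dim(phantom$labels)
  clipped <- any(lo < 1) || any(hi > pd)
  if (clipped) {
    message("crop box clipped at the phantom border for tooth ", tooth_id)
    lo <- pmax(lo, 1)
    hi <- pmin(hi, pd)
  }

  # phantom box -> physical (cm, isocenter origin) -> recon index box
  pp <- phantom$voxel_pitch / 10
  rp <- vol$voxel_pitch / 10
  rd <- dim(vol$values)
  phys_lo <- (lo - 0.5 - pd / 2) * pp
  phys_hi <- (hi + 0.5 - pd / 2) * pp
  vlo <- phys_lo / rp + rd / 2 + 0.5
  vhi <- phys_hi / rp + rd / 2 - 0.5

  out_dims <- rep(as.integer(out_size), 3)
  image <- resample_box_cpp(vol$values, rd, vlo, vhi, out_dims,
                            nearest = FALSE)
  mask_arr <- array(0, dim = pd)
  mask_arr[mask] <- 1
  mask_out <- resample_box_cpp(mask_arr, pd, as.numeric(lo), as.numeric(hi),
                               out_dims, nearest = TRUE)
  storage.mode(mask_out) <- "integer"
  tooth_sample(image, mask_out,
               meta = list(tooth_id = as.integer(tooth_id),
                           crop_lo = lo, crop_hi = hi, margins = margins,
                           clipped = clipped, seed = seed,
                           orientation = c(1L, 2L, 3L),
                           flips = c(FALSE, FALSE, FALSE)))
}

tooth_sample <- function(image, mask, meta = list()) {
  stopifnot(identical(dim(image), dim(mask)))
  if (!any(mask != 0)) stop("tooth sample has an empty mask")
  structure(list(image = image, mask = mask, meta = meta),
            class = "tooth_sample")
}

#' The 48 orientation transforms of a cube
#'
#' All combinations of the 6 axis permutations and 8 per-axis flips, in a
#' fixed order with the identity first.
#'
#' @return A list of 48 transforms, each `list(perm, flips)`.
#' @export
orientation_transforms <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  flips <- expand.grid(f1 = c(FALSE, TRUE), f2 = c(FALSE, TRUE),
                       f3 = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  out <- vector("list", 48)
  k <- 1
  for (p in perms) for (i in seq_len(8)) {
    out[[k]] <- list(perm = as.integer(p),
                     flips = as.logical(flips[i, ]))
    k <- k + 1
  }
  out
}

#' Apply an orientation transform to a 3-D array
#'
#' @param arr a 3-D array (cube).
#' @param transform one element of [orientation_transforms()].
#' @return The permuted/flipped array.
#' @export
apply_orientation <- function(arr, transform) {
  out <- aperm(arr, transform$perm)
  d <- dim(out)
  ix <- if (transform$flips[1]) rev(seq_len(d[1])) else seq_len(d[1])
  iy <- if (transform$flips[2]) rev(seq_len(d[2])) else seq_len(d[2])
  iz <- if (transform$flips[3]) rev(seq_len(d[3])) else seq_len(d[3])
  out[ix, iy, iz, drop = FALSE]
}

#' Orientation-augment a tooth sample
#'
#' Draws `n` distinct transforms (identity first, then seeded sampling
#' without replacement) from the 48-element group of axis permutations and
#' per-axis flips, and applies each to both image and mask.
#'
#' @param sample a `tooth_sample`.
#' @param n number of augmented samples, 1 to 48.
#' @param seed integer seed for the transform draw.
#' @return A list of `n` `tooth_sample`s; the first is the original.
#' @export
augment_orientations <- function(sample, n, seed = NULL) {
  transforms <- orientation_transforms()
  if (n > length(transforms)) {
    stop("at most ", length(transforms),
         " distinct orientation transforms exist")
  }
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  picks <- if (n > 1) c(1L, sample(2:48, n - 1L)) else 1L
  lapply(seq_len(n), function(i) {
    tr <- transforms[[picks[i]]]
    out <- sample
    out$image <- apply_orientation(sample$image, tr)
    out$mask <- apply_orientation(sample$mask, tr)
    out$meta$orientation <- tr$perm
    out$meta$flips <- tr$flips
    out$meta$aug_index <- i
    out
  })
}

#' Write / read a tooth sample
#'
#' Image and mask are written as a NIfTI pair with a JSON metadata sidecar.
#'
#' @param sample a `tooth_sample`.
#' @param dir output directory.
#' @param stem file-name stem.
#' @return The image path, invisibly (write); a `tooth_sample` (read, from
#'   the image path).
#' @export
write_tooth_sample <- function(sample, dir, stem) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img_path <- file.path(dir, paste0(stem, "_image.nii.gz"))
  write_volume(sample$image, img_path)
  write_volume(sample$mask, file.path(dir, paste0(stem, "_mask.nii.gz")),
               integer_type = TRUE)
  jsonlite::write_json(sample$meta, file.path(dir, paste0(stem, ".json")),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(img_path)
}

#' @rdname write_tooth_sample
#' @param path image path written by `write_tooth_sample`.
#' @export
read_tooth_sample <- function(path) {
  stem <- sub("_image\\.nii(\\.gz)?$", "", path)
  image <- read_volume(path)
  mask <- read_volume(paste0(stem, "_mask.nii.gz"))
  attr(image, "pitch") <- NULL
  attr(mask, "pitch") <- NULL
  storage.mode(mask) <- "integer"
  meta <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  tooth_sample(image, mask, meta = as.list(meta))
}

condition_seed <- function(seed, cond, tooth = 0L, aug = 0L) {
  as.integer((as.double(seed) * 2654435 + cond * 40503 + tooth * 9973 +
                aug * 31) %% 2147483629)
}

#' Generate a per-tooth instance segmentation corpus
#'
#' Runs the virtual CBCT pipeline (forward projection, optional noise and
#' cutoff, FDK reconstruction with median filtering) for every condition of
#' the grid, crops every tooth, applies the augmentation policy, and writes
#' the samples with a provenance manifest.  Augmentation draws the first 48
#' variants as distinct orientation transforms of one crop; beyond 48, crop
#' margins are redrawn.  Re-running on a complete output directory is a
#' no-op (completed conditions are skipped via the manifest).
#'
#' @param grid a `condition_grid` whose `phantoms` is a list of
#'   `voxel_phantom`s and `density_sets` a list of multiplier maps.
#' @param out_dir output directory.
#' @param seed global integer seed; every stochastic step derives its own
#'   sub-seed from it.
#' @param geometry `scan_geometry` used for every simulation.
#' @param recon_dim,recon_pitch reconstruction grid (voxels, mm).
#' @param out_size crop cube edge in voxels.
#' @param margin_range per-face crop margin range, phantom voxels.
#' @param filter reconstruction `filter_spec`.
#' @param median_filter apply the 3x3 median to each reconstruction.
#' @return The manifest data frame (one row per sample; failed conditions
#'   are recorded with `status = "failed"`), invisibly written to
#'   `manifest.csv` with a `manifest.json` header.
#' @export
generate_dataset <- function(grid, out_dir, seed = 1,
                             geometry = scan_geometry(detector_cols = 96,
                                                      detector_rows = 64,
                                                      detector_pitch = 1,
                                                      n_projections = 60,
                                                      angular_step = 6),
                             recon_dim = c(64, 64, 64), recon_pitch = 0.2,
                             out_size = 32, margin_range = c(2, 6),
                             filter = filter_spec(), median_filter = TRUE) {
  if (!is.list(grid$phantoms) ||
      !all(vapply(grid$phantoms, inherits, TRUE, "voxel_phantom"))) {
    stop("generate_dataset needs grid$phantoms to be a list of ",
         "voxel_phantom objects")
  }
  if (!is.list(grid$density_sets)) {
    stop("generate_dataset needs grid$density_sets to be a list of ",
         "density multiplier maps (NULL entries = reference)")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  conditions <- enumerate_conditions(grid)
  manifest_path <- file.path(out_dir, "manifest.csv")
  manifest <- if (file.exists(manifest_path)) {
    utils::read.csv(manifest_path, stringsAsFactors = FALSE)
  } else {
    NULL
  }
  done <- unique(manifest$condition)

  pnames <- grid_names(grid$phantoms, "phantom")
  dnames <- grid_names(grid$density_sets, "density")
  new_rows <- list()
  for (ci in conditions$condition) {
    if (ci %in% done) next
    cond <- conditions[ci, ]
    rows <- tryCatch(
      run_condition(grid, cond, pnames, dnames, out_dir, seed, geometry,
                    recon_dim, recon_pitch, out_size, margin_range, filter,
                    median_filter),
      error = function(e) {
        data.frame(sample_id = NA_character_, file = NA_character_,
                   condition = ci, phantom = cond$phantom,
                   density_set = cond$density_set, spectrum = cond$spectrum,
                   noise = cond$noise, cutoff = cond$cutoff,
                   tooth_id = NA_integer_, aug_index = NA_integer_,
                   orientation = NA_character_, flips = NA_character_,
                   crop_seed = NA_integer_, status = "failed",
                   error = conditionMessage(e))
      })
    new_rows[[length(new_rows) + 1]] <- rows
  }
  if (length(new_rows) > 0) {
    new_rows <- do.call(rbind, new_rows)
    if (!("error" %in% names(new_rows))) new_rows$error <- ""
    if (!is.null(manifest) && !("error" %in% names(manifest))) {
      manifest$error <- ""
    }
    manifest <- rbind(manifest, new_rows)
    utils::write.csv(manifest, manifest_path, row.names = FALSE)
    header <- list(seed = seed, counts = as.list(grid$counts),
                   augmentations = grid$augmentations,
                   geometry = unclass(geometry),
                   recon_dim = recon_dim, recon_pitch = recon_pitch,
                   out_size = out_size, margin_range = margin_range)
    jsonlite::write_json(header, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
  }
  invisible(manifest)
}

run_condition <- function(grid, cond, pnames, dnames, out_dir, seed,
                          geometry, recon_dim, recon_pitch, out_size,
                          margin_range, filter, median_filter) {
  ci <- cond$condition
  phantom <- grid$phantoms[[match(cond$phantom, pnames)]]
  dmap <- grid$density_sets[[match(cond$density_set, dnames)]]
  if (!is.null(dmap)) phantom <- vary_densities(phantom, dmap)
  spectrum <- load_spectrum(cond$spectrum)
  stack <- forward_project(phantom, spectrum, geometry)
  if (cond$noise != "none") {
    stack <- add_noise(stack, as.numeric(cond$noise),
                       seed = condition_seed(seed, ci))
  }
  if (cond$cutoff != "none") {
    stack <- apply_cutoff(stack, as.numeric(cond$cutoff))
  }
  vol <- fdk_reconstruct(stack, filter, out_dim = recon_dim,
                         pitch = recon_pitch, median_filter = median_filter)
  rows <- list()
  transforms <- orientation_transforms()
  for (tid in tooth_ids(phantom)) {
    n_crops <- ceiling(grid$augmentations / 48)
    crops <- lapply(seq_len(n_crops), function(m) {
      crop_tooth(vol, phantom, tid, margin_range, out_size,
                 seed = condition_seed(seed, ci, tid, m))
    })
    for (a in seq_len(grid$augmentations)) {
      crop <- crops[[(a - 1) %/% 48 + 1]]
      tr <- transforms[[(a - 1) %% 48 + 1]]
      smp <- crop
      smp$image <- apply_orientation(crop$image, tr)
      smp$mask <- apply_orientation(crop$mask, tr)
      smp$meta$orientation <- tr$perm
      smp$meta$flips <- tr$flips
      smp$meta$aug_index <- a
      smp$meta$condition <- as.list(cond)
      stem <- sprintf("c%03d_t%d_a%02d", ci, tid, a)
      write_tooth_sample(smp, file.path(out_dir, "samples"), stem)
      rows[[length(rows) + 1]] <- data.frame(
        sample_id = stem,
        file = file.path("samples", paste0(stem, "_image.nii.gz")),
        condition = ci, phantom = cond$phantom,
        density_set = cond$density_set, spectrum = cond$spectrum,
        noise = cond$noise, cutoff = cond$cutoff,
        tooth_id = tid, aug_index = a,
        orientation = paste(tr$perm, collapse = ""),
        flips = paste(as.integer(tr$flips), collapse = ""),
        crop_seed = condition_seed(seed, ci, tid, (a - 1) %/% 48 + 1),
        status = "ok", error = "")
    }
  }
  do.call(rbind, rows)
}
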
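#' Trace one ray through a voxel grid
#'
#' Computes the exact voxel-intersection lengths of the segment from the
#' source to a detector pixel center, by incremental parametric (Siddon
#' style) traversal.
#'
#' @param geometry a `scan_geometry`.
#' @param angle projection angle in degrees.
#' @param pixel detector pixel as `c(col, row)` (1-based; fractional values
#'   are allowed).
#' @param dims voxel grid dimensions (length 3).
#' @param pitch voxel pitch in mm (scalar or length 3).
#' @return A data frame with voxel indices `i, j, k` (1-based) and
#'   `length_cm`, ordered from source to detector; zero rows if the ray
#'   misses the volume.
#' @export
trace_ray <- function(geometry, angle, pixel, dims, pitch = 0.2) {
  pixel <- as.numeric(pixel)
  if (pixel[1] < 1 || pixel[1] > geometry$detector_cols ||
      pixel[2] < 1 || pixel[2] > geometry$detector_rows) {
    stop("pixel outside the detector")
  }
  pitch <- rep_len(as.numeric(pitch), 3)
  if (any(pitch <= 0)) stop("voxel pitch must be positive")
  res <- trace_ray_cpp(as.integer(dims), pitch / 10, angle,
                       geometry$source_to_isocenter,
                       geometry$source_to_detector,
                       geometry$detector_cols, geometry$detector_rows,
                       geometry$detector_pitch / 10,
                       geometry$detector_pitch / 10,
                       pixel[1] - 1, pixel[2] - 1)
  data.frame(i = res$i, j = res$j, k = res$k, length_cm = res$length_cm)
}

#' Polychromatic cone-beam forward projection
#'
#' Simulates the intensity ratio I/I0 on every detector pixel for every
#' projection angle: each ray's per-material path lengths are combined with
#' the energy-dependent material attenuation and averaged over the spectrum,
#' giving `sum_E w(E) exp(-sum_j a_ij mu_j(E)) / sum_E w(E)`.  Only direct
#' (unscattered) rays are modelled.
#'
#' @param phantom a `voxel_phantom`.
#' @param spectrum a `spectrum` (see [load_spectrum()]).
#' @param geometry a `scan_geometry`.
#' @return A `projection_stack`: 3-D array of ratios with dimensions
#'   `(detector_cols, detector_rows, n_projections)` plus geometry and
#'   condition metadata.
#' @export
forward_project <- function(phantom, spectrum, geometry) {
  validate_phantom(phantom)
  mats <- phantom$materials
  mu <- mu_matrix(mats, spectrum$energy_keV)
  lut <- rep.int(-1L, max(mats$id) + 1L)
  lut[mats$id + 1L] <- seq_len(nrow(mats)) - 1L
  ratios <- forward_project_cpp(
    phantom$labels, dim(phantom$labels), phantom$voxel_pitch / 10,
    lut, mu, spectrum$weight,
    geometry$source_to_isocenter, geometry$source_to_detector,
    geometry$detector_cols, geometry$detector_rows,
    geometry$detector_pitch / 10, geometry$detector_pitch / 10,
    geometry_angles(geometry))
  projection_stack(ratios, geometry,
                   conditions = list(spectrum = attr(spectrum, "label"),
                                     I0 = NULL, cutoff = NULL))
}

projection_stack <- function(ratios, geometry, conditions = list()) {
  structure(list(ratios = ratios, geometry = geometry,
                 conditions = conditions),
            class = "projection_stack")
}

#' @export
print.projection_stack <- function(x, ...) {
  d <- dim(x$ratios)
  cond <- x$conditions
  cat("<projection_stack> ", d[1], "x", d[2], " pixels, ", d[3], " views\n",
      "  spectrum: ", cond$spectrum %||% "?",
      ", I0: ", if (is.null(cond$I0)) "none" else format(cond$I0),
      ", cutoff: ", if (is.null(cond$cutoff)) "none" else cond$cutoff,
      "\n", sep = "")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Add photon counting noise to a projection stack
#'
#' Converts ratios to expected photon counts `I = I0 * ratio`, perturbs each
#' count with an independent Gaussian of variance I (`I* = I + z sqrt(I)`),
#' and returns the noisy ratios `I*/I0`, floored at a small positive value
#' so that subsequent log transforms remain defined.  Single-shot: noise may
#' not be applied twice.
#'
#' @param stack a noise-free `projection_stack`.
#' @param I0 incident photon count per pixel (e.g. `1e4` or `1e5`).
#' @param seed integer seed making the noise reproducible.
#' @param floor_ratio positive floor applied to the noisy ratios.
#' @return A new `projection_stack` with noisy ratios; the number of floored
#'   pixels is recorded in the conditions metadata.
#' @export
add_noise <- function(stack, I0, seed = NULL, floor_ratio = 1e-6) {
  if (!is.null(stack$conditions$I0)) {
    stop("noise has already been applied to this stack")
  }
  if (I0 <= 0) stop("I0 must be positive")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(as.integer(seed))
  }
  I <- I0 * stack$ratios
  Istar <- I + stats::rnorm(length(I)) * sqrt(I)
  ratios <- Istar / I0
  n_floored <- sum(ratios < floor_ratio)
  if (n_floored > 0) ratios[ratios < floor_ratio] <- floor_ratio
  dim(ratios) <- dim(stack$ratios)
  out <- stack
  out$ratios <- ratios
  out$conditions$I0 <- I0
  out$conditions$noise_seed <- seed
  out$conditions$n_floored <- n_floored
  out
}

#' Clamp projection ratios at a cutoff intensity
#'
#' Replaces every intensity ratio below `c` by `c`, standing in for the
#' limited dynamic range of the detector.  Idempotent.
#'
#' @param stack a `projection_stack`.
#' @param cutoff the cutoff ratio `c`, in (0, 1); the reference device
#'   values are 0.004 and 0.016.
#' @return A new `projection_stack` with clamped ratios.
#' @export
apply_cutoff <- function(stack, cutoff) {
  if (cutoff <= 0 || cutoff >= 1) stop("cutoff must lie in (0, 1)")
  out <- stack
  out$ratios <- pmax(stack$ratios, cutoff)
  dim(out$ratios) <- dim(stack$ratios)
  out$conditions$cutoff <- cutoff
  out
}

#' Projection line integrals
#'
#' Returns `y = -log(I/I0)` per pixel, the attenuation line integrals that
#' feed filtered backprojection.
#'
#' @param stack a `projection_stack` with strictly positive ratios.
#' @return 3-D array of line integrals, same shape as the ratios.
#' @export
line_integrals <- function(stack) {
  if (any(stack$ratios <= 0)) stop("ratios must be strictly positive")
  -log(stack$ratios)
}

#' Write / read a projection stack
#'
#' Projections are stored as a NIfTI volume (cols x rows x angles) with a
#' JSON sidecar holding the geometry and applied conditions.
#'
#' @param stack a `projection_stack`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path` (write) or a `projection_stack` (read).
#' @export
write_projections <- function(stack, path) {
  write_volume(stack$ratios, path, pitch = c(1, 1, 1))
  meta <- list(geometry = unclass(stack$geometry),
               conditions = stack$conditions)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_projections
#' @export
read_projections <- function(path) {
  ratios <- read_volume(path)
  attr(ratios, "pitch") <- NULL
  meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  geom <- do.call(scan_geometry, meta$geometry[
    c("source_to_isocenter", "source_to_detector", "detector_cols",
      "detector_rows", "detector_pitch", "n_projections", "angular_step")])
  projection_stack(ratios, geom, conditions = as.list(meta$conditions))
}

sidecar_path <- function(path) {
  paste0(sub("\\.nii(\\.gz)?$", "", path), ".json")
}
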
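#' Specify a per-tooth deformation
#'
#' @param tooth_id anatomical tooth ID (101-128).
#' @param scale per-axis scale factors, each in (0.5, 2); length 1 or 3.
#' @return A `deformation_spec`.
#' @export
deformation_spec <- function(tooth_id, scale) {
  scale <- rep_len(as.numeric(scale), 3)
  if (any(scale <= 0.5 | scale >= 2.0)) {
    stop("scale factors must lie strictly within (0.5, 2)")
  }
  tooth_id <- as.integer(tooth_id)
  if (tooth_id < 101L || tooth_id > 128L) {
    stop("tooth_id must be an anatomical tooth ID in 101-128")
  }
  structure(list(tooth_id = tooth_id, scale = scale),
            class = "deformation_spec")
}

#' Expand or contract one tooth of a phantom
#'
#' Rescales the named tooth's voxel mask about its centroid by per-axis
#' factors, using nearest-neighbour resampling of the binary mask.  Voxels
#' vacated by contraction take the majority label of their non-tooth
#' 6-neighbourhood; voxels claimed by expansion overwrite any non-tooth
#' label.  Other teeth are never overwritten.
#'
#' @param phantom a `voxel_phantom`.
#' @param spec a `deformation_spec` (or a tooth ID, with `scale` given).
#' @param scale used when `spec` is a bare tooth ID.
#' @return A new `voxel_phantom` with the deformed tooth.
#' @export
#' @examples
#' ph <- build_synthetic_jaw(size = 48, n_teeth = 2, seed = 1)
#' bigger <- deform_tooth(ph, deformation_spec(101, c(1.2, 1, 1)))
deform_tooth <- function(phantom, spec, scale = NULL) {
  if (!inherits(spec, "deformation_spec")) {
    spec <- deformation_spec(spec, scale)
  }
  old_mask <- phantom$tooth_instances == spec$tooth_id
  if (!any(old_mask)) stop("tooth ", spec$tooth_id, " not present in phantom")
  if (all(spec$scale == 1)) return(phantom)

  dims <- dim(phantom$labels)
  idx <- which(old_mask, arr.ind = TRUE)
  centroid <- colMeans(idx)

  # nearest-neighbour resample: new-grid voxel x belongs to the scaled mask
  # iff the original mask holds at round(c + (x - c)/s)
  half <- pmax(apply(abs(sweep(idx, 2, centroid)), 2, max) *
                 pmax(spec$scale, 1) + 2, 3)
  lo <- pmax(floor(centroid - half), 1)
  hi <- pmin(ceiling(centroid + half), dims)
  gx <- lo[1]:hi[1]; gy <- lo[2]:hi[2]; gz <- lo[3]:hi[3]
  sx <- pmin(pmax(round(centroid[1] + (gx - centroid[1]) / spec$scale[1]), 1), dims[1])
  sy <- pmin(pmax(round(centroid[2] + (gy - centroid[2]) / spec$scale[2]), 1), dims[2])
  sz <- pmin(pmax(round(centroid[3] + (gz - centroid[3]) / spec$scale[3]), 1), dims[3])
  new_sub <- old_mask[sx, sy, sz, drop = FALSE]
  new_mask <- array(FALSE, dims)
  new_mask[gx, gy, gz] <- new_sub

  labels <- phantom$labels
  instances <- phantom$tooth_instances
  other_teeth <- labels == phantom$tooth_label &
    instances != spec$tooth_id & instances != 0L
  new_mask <- new_mask & !other_teeth

  vacated <- old_mask & !new_mask
  claimed <- new_mask & !old_mask

  labels[claimed] <- phantom$tooth_label
  instances[new_mask] <- spec$tooth_id
  instances[vacated] <- 0L
  labels[vacated] <- NA_integer_
  labels <- fill_majority(labels, vacated, exclude = phantom$tooth_label)

  out <- phantom
  out$labels <- as_label_array(labels)
  out$tooth_instances <- as_label_array(instances)
  validate_phantom(out)
  out
}

# Iteratively assign NA voxels the majority label among their labelled
# 6-neighbours, excluding `exclude`; ties break to the smallest label.
fill_majority <- function(labels, holes, exclude) {
  dims <- dim(labels)
  while (anyNA(labels)) {
    idx <- which(is.na(labels), arr.ind = TRUE)
    assigned <- FALSE
    for (i in seq_len(nrow(idx))) {
      v <- idx[i, ]
      nb <- integer(0)
      for (ax in 1:3) for (dlt in c(-1L, 1L)) {
        w <- v; w[ax] <- w[ax] + dlt
        if (w[ax] >= 1L && w[ax] <= dims[ax]) {
          lab <- labels[w[1], w[2], w[3]]
          if (!is.na(lab) && lab != exclude) nb <- c(nb, lab)
        }
      }
      if (length(nb) > 0) {
        counts <- table(nb)
        best <- as.integer(names(counts)[counts == max(counts)])
        labels[v[1], v[2], v[3]] <- min(best)
        assigned <- TRUE
      }
    }
    if (!assigned) {
      # isolated cavity fully surrounded by tooth: fall back to air
      labels[is.na(labels)] <- 0L
    }
  }
  labels
}

#' Scale material densities of selected structures
#'
#' Returns a phantom whose material table has densities multiplied by the
#' given per-structure factors; label grids and weight fractions are
#' untouched.  Used to build the "elemental density" variants of the
#' phantom library.
#'
#' @param phantom a `voxel_phantom`.
#' @param factors named numeric vector or list mapping structure ID to a
#'   positive multiplier, e.g. `c("10" = 1.1, "3" = 0.95)`.
#' @return A new `voxel_phantom` sharing the grids, with a scaled table.
#' @export
vary_densities <- function(phantom, factors) {
  factors <- unlist(factors)
  if (is.null(names(factors)) || any(names(factors) == "")) {
    stop("factors must be named by structure ID")
  }
  if (any(factors <= 0)) stop("density multipliers must be positive")
  ids <- as.integer(names(factors))
  unknown <- setdiff(ids, phantom$materials$id)
  if (length(unknown) > 0) {
    stop("multiplier(s) for unknown structure ID(s): ",
         paste(unknown, collapse = ", "))
  }
  mats <- phantom$materials
  i <- match(ids, mats$id)
  mats$density_mg_cm3[i] <- mats$density_mg_cm3[i] * as.numeric(factors)
  out <- phantom
  out$materials <- mats
  out
}
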
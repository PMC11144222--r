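#' Build a procedural synthetic jaw phantom
#'
#' Generates a small jaw-like voxel fixture: a mandible slab (cortical shell,
#' spongiosa core) embedded in soft tissue, with a row of "teeth" formed by
#' ellipsoidal crowns on cylindrical roots anchored in the bone.  Shapes are
#' procedural fixtures, not anatomy; compositions follow the bundled
#' reference material table (bone IDs 3/4, soft tissue ID 8, tooth ID 10
#' with instance IDs 101, 102, ...).  Deterministic for a fixed seed.
#'
#' @param size grid size per axis (scalar or length 3, each >= 32).
#' @param n_teeth number of teeth to place (>= 1).
#' @param seed integer seed controlling the per-tooth jitter.
#' @param pitch voxel pitch in mm (default 0.2, the reference phantom scale).
#' @return A `voxel_phantom`.
#' @export
#' @examples
#' ph <- build_synthetic_jaw(size = 48, n_teeth = 3, seed = 1)
#' tooth_ids(ph)
build_synthetic_jaw <- function(size = 64, n_teeth = 4, seed = 1,
                                pitch = 0.2) {
  dims <- rep_len(as.integer(size), 3)
  if (any(dims < 32)) stop("grid must be at least 32 voxels per axis")
  if (n_teeth < 1) stop("need at least one tooth")
  nx <- dims[1]; ny <- dims[2]; nz <- dims[3]

  # feasibility: teeth are placed on a row along x with >= 1 voxel of
  # separation; each needs a slot of width 2*r_max+2
  margin <- 4L
  slot <- (nx - 2L * margin) %/% n_teeth
  r_max <- (slot - 2L) %/% 2L
  r <- min(r_max, max(2L, nx %/% 12L))
  if (r < 2L) {
    stop("cannot pack ", n_teeth, " teeth into a ", nx,
         "-voxel row: slot width ", slot, " is too small")
  }

  labels <- array(0L, dim = dims)
  instances <- array(0L, dim = dims)
  cx <- seq_len(nx); cy <- seq_len(ny); cz <- seq_len(nz)

  # soft tissue block with a 2-voxel air margin
  soft <- c(3L, 3L, 3L)
  labels[soft[1]:(nx - soft[1] + 1), soft[2]:(ny - soft[2] + 1),
         soft[3]:(nz - soft[3] + 1)] <- 8L

  # mandible slab: lower third of the tissue block, central half in y
  bz <- c(max(soft[3] + 1, round(nz * 0.20)), round(nz * 0.50))
  by <- c(round(ny * 0.30), round(ny * 0.70))
  bx <- c(soft[1] + 1, nx - soft[1])
  labels[bx[1]:bx[2], by[1]:by[2], bz[1]:bz[2]] <- 3L  # cortical
  if (bz[2] - bz[1] > 3 && by[2] - by[1] > 3) {
    labels[(bx[1] + 2):(bx[2] - 2), (by[1] + 2):(by[2] - 2),
           (bz[1] + 2):(bz[2] - 2)] <- 4L  # spongiosa core
  }

  old_seed <- get_rng_state()
  on.exit(restore_rng_state(old_seed))
  set.seed(as.integer(seed))
  jitter_y <- sample(-1:1, n_teeth, replace = TRUE)
  jitter_z <- sample(-1:1, n_teeth, replace = TRUE)

  ymid <- round(ny / 2)
  crown_h <- max(3L, round(r * 1.4))
  root_h <- max(3L, round(r * 1.6))
  for (k in seq_len(n_teeth)) {
    x0 <- margin + (k - 1L) * slot + slot %/% 2L
    y0 <- ymid + jitter_y[k]
    z_top <- bz[2] + jitter_z[k]          # crown center sits above the slab
    zc <- min(nz - soft[3] - crown_h, z_top + crown_h %/% 2L)
    # ellipsoidal crown
    dx2 <- ((cx - x0) / r)^2
    dy2 <- ((cy - y0) / r)^2
    dz2 <- ((cz - zc) / crown_h)^2
    crown <- outer(outer(dx2, dy2, `+`), dz2, `+`) <= 1
    # cylindrical root descending into the bone
    rad2 <- outer((cx - x0)^2, (cy - y0)^2, `+`) <= max(1L, r - 1L)^2
    zroot <- cz >= (zc - crown_h - root_h) & cz <= zc
    root <- outer(rad2, zroot, `&`)
    tooth <- crown | root
    if (any(instances[tooth] != 0L)) {
      stop("tooth packing produced an overlap; reduce n_teeth")
    }
    labels[tooth] <- 10L
    instances[tooth] <- 100L + k
  }

  voxel_phantom(labels, instances, pitch = pitch)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}
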
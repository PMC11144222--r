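#' Construct a voxel phantom
#'
#' A voxel phantom couples an integer structure-label grid with an optional
#' per-tooth instance grid (anatomical tooth IDs 101-128, 0 elsewhere), a
#' voxel pitch in mm, and the material table mapping structure IDs to
#' density and elemental composition.
#'
#' @param labels 3-D integer array of structure IDs.
#' @param instances 3-D integer array of tooth instance IDs (101-128, and 0
#'   outside teeth), same shape as `labels`; `NULL` for a phantom without
#'   tooth instances.
#' @param pitch voxel pitch in mm (scalar or length 3).
#' @param materials a `material_table`; defaults to [reference_materials()].
#' @param tooth_label the structure ID carrying teeth (default 10).
#' @return A `voxel_phantom` object.
#' @export
voxel_phantom <- function(labels, instances = NULL, pitch = 0.2,
                          materials = reference_materials(),
                          tooth_label = 10L) {
  labels <- as_label_array(labels)
  if (is.null(instances)) {
    instances <- array(0L, dim = dim(labels))
  } else {
    instances <- as_label_array(instances)
  }
  pitch <- rep_len(as.numeric(pitch), 3)
  phantom <- structure(
    list(labels = labels, tooth_instances = instances, voxel_pitch = pitch,
         materials = materials, tooth_label = as.integer(tooth_label)),
    class = "voxel_phantom"
  )
  validate_phantom(phantom)
}

as_label_array <- function(x) {
  if (length(dim(x)) != 3) stop("expected a 3-D array")
  storage.mode(x) <- "integer"
  attributes(x) <- list(dim = dim(x))
  x
}

#' Validate a voxel phantom
#'
#' Checks that label and instance grids share a shape, that the pitch is
#' strictly positive, that every label present in the grid has a material
#' row, and that tooth instances are nonzero only on tooth-labelled voxels.
#'
#' @param phantom a `voxel_phantom`.
#' @return The phantom, invisibly; errors on violation.
#' @export
validate_phantom <- function(phantom) {
  if (!identical(dim(phantom$labels), dim(phantom$tooth_instances))) {
    stop("label and instance grids have different shapes")
  }
  if (any(phantom$voxel_pitch <= 0)) stop("voxel pitch must be positive")
  validate_material_table(phantom$materials)
  present <- sort(unique(as.vector(phantom$labels)))
  unknown <- setdiff(present, phantom$materials$id)
  if (length(unknown) > 0) {
    stop("labels with no material row: ", paste(unknown, collapse = ", "))
  }
  stray <- phantom$tooth_instances != 0L & phantom$labels != phantom$tooth_label
  if (any(stray)) {
    stop("tooth instances present on ", sum(stray),
         " voxel(s) not labelled as tooth (ID ", phantom$tooth_label, ")")
  }
  invisible(phantom)
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat("<voxel_phantom> ", paste(dim(x$labels), collapse = " x "),
      " voxels, pitch ", paste(signif(x$voxel_pitch, 3), collapse = "/"),
      " mm\n", sep = "")
  ids <- tooth_ids(x)
  cat("  structures: ", paste(sort(unique(as.vector(x$labels))),
                              collapse = ", "), "\n", sep = "")
  cat("  teeth: ", if (length(ids)) paste(ids, collapse = ", ") else "none",
      "\n", sep = "")
  invisible(x)
}

#' Tooth instance IDs present in a phantom
#'
#' @param phantom a `voxel_phantom`.
#' @return Sorted integer vector of anatomical tooth IDs (101-128).
#' @export
tooth_ids <- function(phantom) {
  ids <- sort(unique(as.vector(phantom$tooth_instances)))
  ids[ids != 0L]
}

#' Load a voxel phantom from volume files and a material CSV
#'
#' @param label_path NIfTI (`.nii`/`.nii.gz`) or MetaImage (`.mhd`) label
#'   volume.
#' @param material_path material table CSV
#'   (`id,name,icrp_id,density_mg_cm3,wH,...`).
#' @param instance_path optional tooth-instance volume, same grid as the
#'   labels.
#' @param pitch optional voxel pitch (mm) overriding the file header.
#' @return A validated `voxel_phantom`.
#' @export
load_phantom <- function(label_path, material_path, instance_path = NULL,
                         pitch = NULL) {
  labels <- read_volume(label_path)
  header_pitch <- attr(labels, "pitch")
  instances <- if (!is.null(instance_path)) read_volume(instance_path)
  materials <- read_material_table(material_path)
  if (is.null(pitch)) {
    pitch <- if (!is.null(header_pitch) && all(header_pitch > 0)) {
      header_pitch
    } else {
      0.2
    }
  }
  voxel_phantom(labels, instances, pitch = pitch, materials = materials)
}

#' Save a voxel phantom
#'
#' Writes `<stem>_labels`, `<stem>_instances` (both NIfTI or MetaImage
#' depending on `format`) and `<stem>_materials.csv` into `dir`.
#'
#' @param phantom a `voxel_phantom`.
#' @param dir output directory (created if needed).
#' @param stem file-name stem (default `"phantom"`).
#' @param format `"nifti"` or `"mhd"`.
#' @return Named character vector of the three paths written, invisibly.
#' @export
save_phantom <- function(phantom, dir, stem = "phantom", format = "nifti") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ext <- switch(match.arg(format, c("nifti", "mhd")),
                nifti = ".nii.gz", mhd = ".mhd")
  paths <- c(
    labels = file.path(dir, paste0(stem, "_labels", ext)),
    instances = file.path(dir, paste0(stem, "_instances", ext)),
    materials = file.path(dir, paste0(stem, "_materials.csv"))
  )
  write_volume(phantom$labels, paths[["labels"]],
               pitch = phantom$voxel_pitch, integer_type = TRUE)
  write_volume(phantom$tooth_instances, paths[["instances"]],
               pitch = phantom$voxel_pitch, integer_type = TRUE)
  write_material_table(phantom$materials, paths[["materials"]])
  invisible(paths)
}
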
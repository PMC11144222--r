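#' Read a 3-D volume from NIfTI or MetaImage
#'
#' Supports NIfTI-1 (`.nii`, `.nii.gz`) through RNifti and MetaImage
#' (`.mhd` + raw) through a minimal built-in reader.  Returns the voxel
#' array with the per-axis spacing (mm) attached as attribute `pitch`.
#'
#' @param path path to a `.nii`, `.nii.gz` or `.mhd` file.
#' @return A 3-D array with attribute `pitch` (numeric length 3, mm).
#' @export
read_volume <- function(path) {
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    return(read_mhd(path))
  }
  img <- RNifti::readNifti(path)
  arr <- array(as.vector(img), dim = dim(img))
  attr(arr, "pitch") <- RNifti::pixdim(img)[seq_len(3)]
  arr
}

#' Write a 3-D volume to NIfTI or MetaImage
#'
#' @param vol a 3-D array.
#' @param path output path ending in `.nii`, `.nii.gz` or `.mhd`.
#' @param pitch per-axis voxel spacing in mm (length 1 or 3).
#' @param integer_type write integer voxels (used for label grids).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, pitch = c(1, 1, 1), integer_type = FALSE) {
  pitch <- rep_len(as.numeric(pitch), 3)
  if (grepl("\\.mhd$", path, ignore.case = TRUE)) {
    return(write_mhd(vol, path, pitch, integer_type))
  }
  storage.mode(vol) <- if (integer_type) "integer" else "double"
  img <- RNifti::asNifti(vol)
  img <- RNifti::`pixdim<-`(img, pitch)
  RNifti::writeNifti(img, path,
                     datatype = if (integer_type) "int32" else "double")
  invisible(path)
}

# Minimal MetaImage support: enough of the .mhd dialect for label and
# intensity volumes (MET_INT / MET_SHORT / MET_UCHAR / MET_FLOAT /
# MET_DOUBLE, little-endian, single raw file).
read_mhd <- function(path) {
  lines <- readLines(path, warn = FALSE)
  kv <- strsplit(lines, "\\s*=\\s*")
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, function(x) paste(x[-1], collapse = " "), "")
  get <- function(key, default = NULL) {
    i <- match(tolower(key), tolower(keys))
    if (is.na(i)) default else vals[i]
  }
  ndims <- as.integer(get("NDims", "3"))
  if (ndims != 3) stop("only 3-D MetaImage volumes are supported")
  dims <- as.integer(strsplit(get("DimSize"), "\\s+")[[1]])
  pitch <- as.numeric(strsplit(get("ElementSpacing", "1 1 1"), "\\s+")[[1]])
  msb <- toupper(get("ElementByteOrderMSB", "False")) == "TRUE"
  type <- get("ElementType", "MET_FLOAT")
  spec <- switch(type,
    MET_UCHAR = list(what = "integer", size = 1, signed = FALSE),
    MET_SHORT = list(what = "integer", size = 2, signed = TRUE),
    MET_INT = list(what = "integer", size = 4, signed = TRUE),
    MET_FLOAT = list(what = "double", size = 4, signed = TRUE),
    MET_DOUBLE = list(what = "double", size = 8, signed = TRUE),
    stop("unsupported ElementType: ", type)
  )
  raw_file <- get("ElementDataFile")
  if (is.null(raw_file) || toupper(raw_file) == "LOCAL") {
    stop("only ElementDataFile pointing to a raw file is supported")
  }
  raw_path <- file.path(dirname(path), raw_file)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(dims)
  data <- readBin(con, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed,
                  endian = if (msb) "big" else "little")
  arr <- array(data, dim = dims)
  attr(arr, "pitch") <- rep_len(pitch, 3)
  arr
}

write_mhd <- function(vol, path, pitch, integer_type) {
  raw_name <- sub("\\.mhd$", ".raw", basename(path), ignore.case = TRUE)
  type <- if (integer_type) "MET_INT" else "MET_DOUBLE"
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "ElementByteOrderMSB = False",
    paste("DimSize =", paste(dim(vol), collapse = " ")),
    paste("ElementSpacing =", paste(pitch, collapse = " ")),
    paste("ElementType =", type),
    paste("ElementDataFile =", raw_name)
  )
  writeLines(header, path)
  con <- file(file.path(dirname(path), raw_name), "wb")
  on.exit(close(con))
  if (integer_type) {
    writeBin(as.integer(vol), con, size = 4, endian = "little")
  } else {
    writeBin(as.double(vol), con, size = 8, endian = "little")
  }
  invisible(path)
}
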
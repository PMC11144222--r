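#' Reference material table for the dental head phantom
#'
#' Returns the bundled table of anatomical structures with their ICRP
#' reference IDs, mass densities and elemental weight fractions
#' (H, C, N, O, P, Ca).  Eleven structures are defined (structure ID 7 is
#' unused): air, three cortical and three spongiosa bone compartments,
#' residual tissue, skin, tooth and air inside the body.  Densities are in
#' mg/cm^3 and weight fractions in percent.
#'
#' @return A `material_table`: a data frame with columns `id`, `name`,
#'   `icrp_id`, `density_mg_cm3`, and `wH`..`wCa` (percent), one row per
#'   structure ID.
#' @export
#' @examples
#' mats <- reference_materials()
#' mats[mats$id == 10, "density_mg_cm3"]  # tooth: 2750
reference_materials <- function() {
  path <- system.file("extdata", "materials_table2.csv", package = "vcbct",
                      mustWork = TRUE)
  read_material_table(path)
}

#' Read a material table from CSV
#'
#' The expected header is
#' `id,name,icrp_id,density_mg_cm3,wH,wC,wN,wO,wP,wCa` with densities in
#' mg/cm^3 and elemental weight fractions in percent.
#'
#' @param path path to a CSV file.
#' @return A validated `material_table` data frame.
#' @export
read_material_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("id", "name", "icrp_id", "density_mg_cm3",
                "wH", "wC", "wN", "wO", "wP", "wCa")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0) {
    stop("material table is missing columns: ", paste(missing, collapse = ", "))
  }
  tab <- tab[required]
  class(tab) <- c("material_table", "data.frame")
  validate_material_table(tab)
  tab
}

#' Write a material table to CSV
#'
#' @param materials a `material_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_material_table <- function(materials, path) {
  validate_material_table(materials)
  utils::write.csv(as.data.frame(materials), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a material table
#'
#' Checks the invariants of the material model: weight fractions per row sum
#' to 100 within 1.0 (the reference table is printed to one decimal and its
#' rows sum to between 99.2 and 100), densities are strictly positive, and
#' structure IDs are unique.
#'
#' @param materials a `material_table`.
#' @return `materials`, invisibly; errors on violation.
#' @export
validate_material_table <- function(materials) {
  if (anyDuplicated(materials$id)) {
    stop("duplicated structure IDs in material table")
  }
  frac_sum <- rowSums(materials[element_columns()])
  bad <- abs(frac_sum - 100) > 1.0
  if (any(bad)) {
    stop("weight fractions do not sum to 100 +/- 1 for ID(s): ",
         paste(materials$id[bad], collapse = ", "))
  }
  if (any(materials$density_mg_cm3 <= 0)) {
    stop("non-positive density for ID(s): ",
         paste(materials$id[materials$density_mg_cm3 <= 0], collapse = ", "))
  }
  invisible(materials)
}

element_columns <- function() c("wH", "wC", "wN", "wO", "wP", "wCa")
element_symbols <- function() c("H", "C", "N", "O", "P", "Ca")

material_row <- function(materials, id) {
  i <- match(id, materials$id)
  if (is.na(i)) stop("no material row for structure ID ", id)
  materials[i, , drop = FALSE]
}
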
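# Energy-dependent linear attenuation for mixture materials: each material's
# mu(E) is the density times the weight-fraction-averaged elemental mass
# attenuation, with the elemental coefficients tabulated per interaction
# process (photoelectric, Compton, Rayleigh) on a 1-keV grid.

the_elements <- new.env(parent = emptyenv())

#' Per-element mass attenuation table
#'
#' Returns the bundled table of elemental mass attenuation coefficients
#' (cm^2/g) for H, C, N, O, P and Ca on a 1-keV grid over 10-120 keV,
#' decomposed into photoelectric, Compton and Rayleigh contributions.  The
#' factor Z N_A / A converting per-atom cross sections to mass attenuation
#' is already absorbed into the tabulated values.
#'
#' @param path optional CSV path overriding the bundled table (columns
#'   `element,Z,A,energy_keV,mu_over_rho_pe,mu_over_rho_compton,`
#'   `mu_over_rho_rayleigh`).
#' @return Data frame with one row per element and energy bin.
#' @export
element_attenuation <- function(path = NULL) {
  if (is.null(path)) {
    if (!is.null(the_elements$table)) return(the_elements$table)
    path <- system.file("extdata", "element_mu.csv", package = "vcbct",
                        mustWork = TRUE)
    the_elements$table <- utils::read.csv(path)
    return(the_elements$table)
  }
  utils::read.csv(path)
}

# total mu/rho (cm^2/g) matrix: rows = elements in element_symbols() order,
# cols = requested energies (must be on the table grid)
element_mu_over_rho <- function(energies) {
  tab <- element_attenuation()
  grid <- sort(unique(tab$energy_keV))
  e <- check_energies(energies, grid)
  syms <- element_symbols()
  out <- matrix(0, nrow = length(syms), ncol = length(e),
                dimnames = list(syms, NULL))
  for (s in syms) {
    sub <- tab[tab$element == s, ]
    total <- sub$mu_over_rho_pe + sub$mu_over_rho_compton +
      sub$mu_over_rho_rayleigh
    out[s, ] <- total[match(e, sub$energy_keV)]
  }
  out
}

check_energies <- function(energies, grid) {
  if (any(energies < min(grid) - 0.5 | energies > max(grid) + 0.5)) {
    stop("energy out of the tabulated range [", min(grid), ", ", max(grid),
         "] keV; no extrapolation is performed")
  }
  e <- round(energies)
  off <- abs(energies - e) > 1e-9
  if (any(off)) {
    warning("off-grid energies rounded to the nearest 1-keV bin: ",
            paste(signif(energies[off], 4), collapse = ", "))
  }
  e
}

#' Linear attenuation coefficient of a material
#'
#' Computes mu(E) = rho * sum_m w_m (mu/rho)_m(E) with weight fractions
#' taken as mass fractions (table percent / 100) and density converted from
#' mg/cm^3 to g/cm^3; the result is linear in density.
#'
#' @param material one row of a `material_table`, or a structure ID to be
#'   looked up in `materials`.
#' @param energy photon energies in keV (within the tabulated 10-120 keV).
#' @param materials table used when `material` is given as an ID.
#' @return Numeric vector of linear attenuation coefficients, 1/cm.
#' @export
#' @examples
#' mats <- reference_materials()
#' mu_material(10, 60, mats)   # tooth at 60 keV
mu_material <- function(material, energy, materials = reference_materials()) {
  if (!is.data.frame(material)) {
    material <- material_row(materials, material)
  }
  w <- as.numeric(material[1, element_columns()]) / 100
  rho <- material$density_mg_cm3[1] / 1000  # g/cm^3
  mor <- element_mu_over_rho(energy)
  as.numeric(rho * (w %*% mor))
}

#' Attenuation map of a phantom at one energy
#'
#' Maps each voxel's structure label to its linear attenuation coefficient.
#'
#' @param phantom a `voxel_phantom`.
#' @param energy a single photon energy in keV.
#' @return 3-D array of mu values (1/cm), same shape as the label grid.
#' @export
mu_volume <- function(phantom, energy) {
  stopifnot(length(energy) == 1)
  mats <- phantom$materials
  mu_by_id <- vapply(seq_len(nrow(mats)), function(i) {
    mu_material(mats[i, , drop = FALSE], energy)
  }, numeric(1))
  lut <- numeric(max(mats$id) + 1L)
  lut[mats$id + 1L] <- mu_by_id
  out <- array(lut[phantom$labels + 1L], dim = dim(phantom$labels))
  out
}

# mu lookup matrix for the projector: rows = material table rows (by id
# order), cols = spectrum energies
mu_matrix <- function(materials, energies) {
  mor <- element_mu_over_rho(energies)
  w <- as.matrix(materials[element_columns()]) / 100
  rho <- materials$density_mg_cm3 / 1000
  sweep(w %*% mor, 1, rho, `*`)
}
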
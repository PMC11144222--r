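#' Load an X-ray spectrum
#'
#' Loads one of the bundled tube spectra, a monoenergetic test spectrum, or
#' a user CSV.  Bundled spectra (1-keV bins): `"soft-90kVp"` (90 kVp,
#' 2.5 mm Al), `"hard-90kVp"` (90 kVp, 6.5 mm Al) and `"100kVp"` (100 kVp,
#' 6.5 mm Al).  Names of the form `"mono-<E>"` give a single-bin spectrum
#' at `<E>` keV.  A CSV must have columns `energy_keV,weight`.
#'
#' @param name_or_path spectrum name or CSV path.
#' @param normalize if `TRUE` (default) rescale weights to sum to 1.
#' @return A `spectrum` object: data frame with columns `energy_keV` and
#'   `weight`, attribute `label`.
#' @export
#' @examples
#' sp <- load_spectrum("hard-90kVp")
#' mean_energy(sp)
load_spectrum <- function(name_or_path, normalize = TRUE) {
  label <- name_or_path
  if (grepl("^mono-[0-9]+$", name_or_path)) {
    e <- as.integer(sub("^mono-", "", name_or_path))
    tab <- data.frame(energy_keV = e, weight = 1)
  } else if (file.exists(name_or_path)) {
    tab <- utils::read.csv(name_or_path)
    label <- sub("\\.csv$", "", basename(name_or_path))
  } else {
    path <- system.file("extdata", "spectra", paste0(name_or_path, ".csv"),
                        package = "vcbct")
    if (!nzchar(path)) {
      stop("unknown spectrum '", name_or_path, "'; bundled spectra: ",
           paste(list_spectra(), collapse = ", "),
           "; or use mono-<E> or a CSV path")
    }
    tab <- utils::read.csv(path)
  }
  if (!all(c("energy_keV", "weight") %in% names(tab))) {
    stop("spectrum file must have columns energy_keV,weight")
  }
  as_spectrum(tab$energy_keV, tab$weight, label, normalize)
}

#' List the bundled spectrum names
#' @return Character vector of spectrum names usable with [load_spectrum()].
#' @export
list_spectra <- function() {
  files <- list.files(system.file("extdata", "spectra", package = "vcbct"),
                      pattern = "\\.csv$")
  sub("\\.csv$", "", files)
}

as_spectrum <- function(energy, weight, label, normalize = TRUE) {
  ord <- order(energy)
  energy <- as.numeric(energy[ord]); weight <- as.numeric(weight[ord])
  if (any(weight < 0)) stop("spectrum weights must be non-negative")
  if (sum(weight) <= 0) stop("spectrum must have at least one positive bin")
  if (anyDuplicated(energy)) stop("duplicated energy bins")
  if (length(energy) > 1 && any(abs(diff(energy) - 1) > 1e-9)) {
    stop("spectrum must be tabulated on a uniform 1-keV grid")
  }
  if (normalize) weight <- weight / sum(weight)
  structure(data.frame(energy_keV = energy, weight = weight),
            label = label, class = c("spectrum", "data.frame"))
}

#' Mean energy of a spectrum
#'
#' Fluence-weighted mean photon energy in keV; harder (more filtered) beams
#' have higher mean energy.
#'
#' @param spectrum a `spectrum`.
#' @return Mean energy, keV.
#' @export
mean_energy <- function(spectrum) {
  sum(spectrum$energy_keV * spectrum$weight) / sum(spectrum$weight)
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", attr(x, "label"), ": ", nrow(x), " bins, ",
      min(x$energy_keV), "-", max(x$energy_keV), " keV, mean ",
      round(mean_energy(x), 1), " keV\n", sep = "")
  invisible(x)
}
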
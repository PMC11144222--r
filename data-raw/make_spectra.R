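# One-time generation of the bundled X-ray tube spectra
# (inst/extdata/spectra/*.csv): Kramers bremsstrahlung n(E) ~ (E_max - E)/E on
# a 1-keV grid, attenuated by an aluminium filter of the stated thickness.
# Tungsten characteristic lines are not modelled.  Aluminium attenuation uses
# the same analytic process model as data-raw/make_element_table.R.
#
#   soft-90kVp : 90 kVp, 2.5 mm Al
#   hard-90kVp : 90 kVp, 6.5 mm Al
#   100kVp     : 100 kVp, 6.5 mm Al

N_A <- 6.02214076e23
r_e <- 2.8179403262e-13
mec2 <- 510.99895

klein_nishina <- function(E_keV) {
  k <- E_keV / mec2
  2 * pi * r_e^2 * (
    (1 + k) / k^2 * (2 * (1 + k) / (1 + 2 * k) - log(1 + 2 * k) / k) +
      log(1 + 2 * k) / (2 * k) - (1 + 3 * k) / (1 + 2 * k)^2
  )
}

tau0 <- 5.09e-24 * 30^3.1 / 8^4.4
r0   <- 3.60e-25 * 30^1.9 / 8^2.5

mu_over_rho_Al <- function(E) {
  Z <- 13; A <- 26.982
  (tau0 * Z^4.4 / E^3.1 + Z * klein_nishina(E) + r0 * Z^2.5 / E^1.9) * N_A / A
}

make_spectrum <- function(kvp, al_mm) {
  E <- 10:kvp
  raw <- (kvp - E) / E
  filt <- exp(-mu_over_rho_Al(E) * 2.699 * al_mm / 10)
  w <- raw * filt
  data.frame(energy_keV = E, weight = signif(w / max(w), 6))
}

dir.create("inst/extdata/spectra", showWarnings = FALSE, recursive = TRUE)
write.csv(make_spectrum(90, 2.5), "inst/extdata/spectra/soft-90kVp.csv",
          row.names = FALSE, quote = FALSE)
write.csv(make_spectrum(90, 6.5), "inst/extdata/spectra/hard-90kVp.csv",
          row.names = FALSE, quote = FALSE)
write.csv(make_spectrum(100, 6.5), "inst/extdata/spectra/100kVp.csv",
          row.names = FALSE, quote = FALSE)
cat("spectra written\n")
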
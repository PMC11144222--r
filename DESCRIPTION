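Package: vcbct
Title: Virtual Dental Cone-Beam CT Simulation and Tooth Instance Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A virtual cone-beam computed tomography (CBCT) system for
    dentistry: voxel phantoms with ICRP-style elemental material
    compositions, polychromatic material-based forward projection with
    photon noise and detector cutoff, Feldkamp-Davis-Kress (FDK)
    reconstruction with a parameterized windowed ramp filter, a dataset
    factory that turns phantom variants and scan conditions into a
    labeled per-tooth instance-segmentation corpus, and a native 3D
    U-Net for per-tooth binary segmentation with Dice evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
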
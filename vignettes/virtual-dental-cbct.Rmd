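---
title: "Virtual dental CBCT: physics model, dataset factory and segmentation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Virtual dental CBCT: physics model, dataset factory and segmentation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vcbct` is a virtual cone-beam CT (CBCT) system for dentistry. It scans a
labeled voxel phantom with a physics-based polychromatic projector,
reconstructs the scan with the Feldkamp–Davis–Kress (FDK) algorithm, and
turns phantom variants crossed with scan conditions into a per-tooth
instance-segmentation training corpus, on which a native 3D U-Net can be
trained and evaluated with the Dice similarity coefficient (DSC). Because
the ground-truth tooth masks come from the phantom itself, the corpus is
free of manual-contouring ambiguity.

This vignette documents the model and its assumptions, the tunable
parameters, the numerical choices, and what the synthetic fixtures do and
do not establish about real data.

## The phantom and material model

A `voxel_phantom` couples an integer structure-label grid with a per-tooth
instance grid (anatomical tooth IDs 101–128 on tooth-labeled voxels), a
voxel pitch in mm, and a material table. The reference table
(`reference_materials()`) has eleven structures — air, three cortical and
three spongiosa bone compartments, residual tissue, skin, tooth, and air
inside the body — each with an ICRP-style mass density (mg/cm³) and weight
fractions of H, C, N, O, P and Ca in percent. Structure ID 7 is unused in
the reference numbering, and the printed air density of 1 mg/cm³ is kept
as-is rather than silently corrected to the physical 1.2 mg/cm³. The
printed weight-fraction rows sum to between 99.2 and 100 because of
one-decimal rounding; the validator therefore accepts row sums within ±1 of
100.

The reference head phantom this table describes is a 0.2 mm-pitch grid
(its published description mixes a "cm" unit into the pitch, which would
imply a two-metre head; the toolkit treats pitch as 0.2 mm and is otherwise
size-agnostic, reading the grid from the file).

The phantom library is expanded in two ways:

* `deform_tooth()` rescales one tooth's binary mask about its centroid by
  per-axis factors in (0.5, 2), using nearest-neighbour resampling. The
  fill rule for voxels vacated by contraction is not dictated by the
  physics, so a parameter-free and reproducible rule is used: the majority
  label of the non-tooth 6-neighbourhood, ties to the smallest label;
  voxels claimed by expansion overwrite any non-tooth label, and other
  teeth are never overwritten.
* `vary_densities()` multiplies selected structures' densities, leaving
  grids and weight fractions untouched — this realizes the "elemental
  density" variants of the corpus. The specific factor sets used for the
  reference corpus are not published; they are a user choice.

`build_synthetic_jaw()` generates the test fixture used throughout the
package: ellipsoidal crowns on cylindrical roots in a cortical/spongiosa
mandible slab inside soft tissue. These are *fixtures*, not anatomy — they
carry realistic compositions and instance structure but no anatomical
shape detail (no enamel/dentin substructure, no root branching).

## X-ray physics

The projector implements material-based forward projection: for detector
pixel $i$,

$$\frac{I_i}{I_0} \;=\; \frac{\sum_E \alpha(E)\,n_0(E)\,
  e^{-\sum_j a_{ij}\,\mu_j(E)}}{\sum_E \alpha(E)\,n_0(E)},$$

where $a_{ij}$ is the exact intersection length of ray $i$ with voxel $j$
(incremental parametric/Siddon traversal) and the energy grid is 1 keV.
Each voxel's attenuation is the mixture rule
$\mu_j(E) = \rho_j \sum_m w_m (\mu/\rho)_m(E)$ over the six elements, with
the per-element mass attenuation decomposed into photoelectric, Compton
and Rayleigh contributions (`inst/extdata/element_mu.csv`, 10–120 keV).
The factor $Z N_A / A$ that converts per-atom cross sections to mass
attenuation is absorbed into the tabulated values.

The bundled element table is generated from analytic standard models: the
exact Klein–Nishina total cross section (free-electron approximation) for
incoherent scattering, and smooth power-law parameterizations
($\sigma_{pe}\propto Z^{4.4}/E^{3.1}$,
$\sigma_{Rayl}\propto Z^{2.5}/E^{1.9}$) calibrated at light-element
anchors for the other two processes (`data-raw/make_element_table.R`).
These forms are K-edge-free, which is exact for H–Ca above 10 keV, and are
accurate at the tens-of-percent level — adequate for generating realistic
image contrast and beam hardening, and swappable for any user-supplied
table via the same CSV format. All attenuation tests in the package are
internal-consistency oracles (independent dot-product paths over the same
table), deliberately, so that the simulation physics is checked separately
from the accuracy of any particular cross-section tabulation.

Three tube spectra ship with the package — soft-90kVp (2.5 mm Al),
hard-90kVp (6.5 mm Al) and 100kVp (6.5 mm Al) — generated once with a
Kramers bremsstrahlung model filtered through the same analytic aluminium
attenuation (`data-raw/make_spectra.R`). Tungsten characteristic lines are
not modelled. These are approximations with the stated peak voltage and
filtration, not the reference device's proprietary spectra; `mono-<E>`
names give single-bin test spectra, and any CSV with
`energy_keV,weight` columns can be dropped in. Off-grid energies round to
the nearest 1-keV bin with a warning; energies outside 10–120 keV are
errors, never extrapolated.

## Scan geometry, noise and cutoff

The default `scan_geometry()` mirrors a typical dental CBCT device: 30 cm
source-to-isocenter, 55 cm source-to-detector, a 2000 × 1000 flat panel at
0.2 mm pitch, 360 projections at 1° steps. Geometry is entirely
configuration-driven; the tests use scaled detectors (e.g. 96 × 64, 40–90
views) for speed, and those scaled sizes are stated in each test. The
angle convention — projection $k$ at $k\cdot\Delta\beta$ degrees,
counterclockwise about $+z$, source on $+x$ at angle 0 — is fixed by the
package since any convention is internally consistent.

Photon noise follows $I^* = I + z\sqrt{I}$ with standard-normal $z$,
i.e. a Gaussian approximation to Poisson counting noise with
$\mathrm{Var}(I^*) = I$; the noise level is set by the incident count
$I_0 \in \{10^4, 10^5\}$ in the reference conditions. Noisy ratios are
floored at $10^{-6}$ so logarithms stay finite (the floored-pixel count is
recorded). Noise is single-shot: applying it twice is an error, not a
warning, because the variance model would silently double.

Detector response is not modelled; following the reference device
conditions, a cutoff intensity $c$ (0.004 or 0.016) clamps every ratio
from below, standing in for the limited detector dynamic range. Noise is
applied before cutoff, in that order, matching the order the conditions
are described in; both transforms are optional and recorded in the stack's
metadata.

## FDK reconstruction

`fdk_reconstruct()` is a standard voxel-driven FDK: line integrals
$y = -\ln(I/I_0)$ are cosine-weighted per pixel, filtered row-wise in the
frequency domain (zero-padded to the next power of two ≥ twice the row
length for linear-convolution correctness), and backprojected with
bilinear detector interpolation and inverse-square distance weights scaled
by the angular increment.

The reconstruction filter is a windowed ramp for divergent beams,

$$H(\nu) = |\nu|\left[\alpha + (1-\alpha)\cos\!\frac{\pi\nu}{\gamma\,\nu_N}\right]
  \quad (|\nu| \le W\nu_N),\qquad 0 \text{ otherwise},$$

with Nyquist $\nu_N = 0.5$ cycles/sample and defaults $\alpha = 0.54$,
$\gamma = 1.0$, $W = 0.8$ — Hamming-style apodization with a hard cutoff
at 80 % of Nyquist. The exact analytic form of the divergent-beam filter
these parameters originate from is not published alongside them, so this
realization is one defensible reading; it sits behind `ramp_window()` /
`filter_spec()` so an alternative can be swapped in without touching the
backprojector. Reconstructed values are effective linear attenuation in
1/cm on the spectrum's scale; no Hounsfield conversion is performed.

A 3 × 3 median filter (`median_filter_3x3()`) suppresses view-aliasing
streaks. "3 × 3" is read as two-dimensional per axial slice, since it is
described as acting on the image; a 3 × 3 × 3 volumetric variant is
available via `mode = "3d"` for users who read it the other way.

FDK correctness is established against analytic oracles: a monoenergetic
homogeneous cylinder must reconstruct its known $\mu$ at the centre
(within 10 %, flat to ±10 % inside half the radius), an empty scan must
reconstruct to ~0, doubling density must double the reconstruction, and
more views must reduce the error against the attenuation map.

## The dataset factory

`condition_grid()` describes the corpus: $P$ phantoms × $D$ density sets
× $S$ spectra × $N$ noise levels × $C$ cutoffs, with $A$ augmentations
per tooth. The reference corpus is $7 \times 2 \times 3 \times 3 = 126$
imaging conditions, 27 teeth per phantom, and a total of 170,100 samples.
That total factorizes two ways: $126 \times 27 \times 50$ (one cutoff
setting, $A = 50$) or $252 \times 27 \times 25$ (both cutoffs in the
grid, $A = 25$). The condition enumeration that defines the corpus lists
spectra and noise but not cutoffs, so the first factorization is the
default; both are expressible, and `count_samples()` verifies either
arithmetic without generating data.

Each tooth is cropped from the reconstruction at its instance bounding
box, expanded per-face by a seeded uniform integer margin (default 2–10
voxels at full scale; the exact range used for the reference corpus is
unpublished), and resampled to a cube — 128³ at full scale, 32³ in the
desk-scale configurations. Images resample trilinearly, masks by nearest
neighbour, and the mask keeps only the target tooth even when neighbours
enter the box. Orientation augmentation draws without replacement from
the 48-element group of axis permutations × per-axis flips, identity
first; when $A > 48$, the surplus draws redraw crop margins instead, so
samples stay distinct. Every sample carries full provenance (condition
tuple, transform, margins, derived seed) in the manifest and is
regenerable bit-exactly from the global seed; generation is resumable and
failed conditions are recorded rather than aborting the run.

Samples are stored as NIfTI image/mask pairs with JSON sidecars plus a
`manifest.csv`, so a corpus is inspectable with any standard imaging
viewer.

## The segmentation model

`build_unet()` constructs a 3D U-Net natively in R: feature maps are
C × n_vox matrices and each 3 × 3 × 3 convolution is a single
BLAS GEMM against an im2col matrix (C++). The encoding path downsamples
with 3 × 3 × 3 stride-2 convolutions (batch norm, then LeakyReLU, default
slope 0.01); all other convolutions use batch norm and ReLU; the
expansive path restores resolution with 2 × 2 × 2 nearest-neighbour
upsampling and skip concatenation; a 1 × 1 × 1 convolution and sigmoid
produce a single-channel probability map thresholded at 0.5 (ties to
foreground). Gradients are computed by hand-written backpropagation and
verified against central finite differences in the test suite.

Training follows the resampled-round protocol: per round, draw
`round_size` samples from the corpus, split them (default 80/20) into
training and model-selection subsets, optimize a soft-Dice loss with Adam
for `epochs_per_round` epochs keeping the best-validation weights, then
redraw; the reference protocol is 500 samples per round, ~50 epochs per
round and ~2000 in total. Optimizer, loss and learning rate are not
published for the reference model; soft-Dice + Adam is the field-standard
choice for this head. The defaults are the reference-scale values
(learning rate 1e-4, batch 2); the desk-scale configurations in the tests
and acceptance script use a 32³ input, 3 levels, 4 base channels and a
learning rate of 1e-2, which this small network needs to converge in tens
of epochs. Inputs are z-score normalized per sample.

## Desk-scale study and what it shows

The full-scale corpus (1000³ phantom, 2000 × 1000 detector, 360 views,
128³ crops, 170,100 samples, ~2000 epochs) is far beyond a desk CPU; the
package therefore ships a scaled study used by both the test suite and
`scripts/acceptance.R`: a 48³ jaw fixture with 3 teeth, one spectrum with
photon noise at $I_0 = 10^5$, a 96 × 72 detector with 60 views, 48³
reconstruction, 32³ crops with 8 orientation augmentations (24 samples),
and 30–45 training epochs with one tooth held out entirely. Held-out
DSC in this configuration lands in the mid-to-high 0.9s, consistent with
near-perfect virtual-to-virtual segmentation at full scale.

What this does and does not show: the fixtures exercise the full pipeline
— polychromatic attenuation contrast, photon noise, reconstruction
artifacts, per-tooth cropping, orientation augmentation, tooth-level
holdout — so a high held-out DSC demonstrates that the corpus is
learnable and the model/protocol implementation is sound. It does *not*
demonstrate clinical transfer: real scanners add detector response,
scatter, motion and anatomy far richer than ellipsoid-and-cylinder teeth,
and evaluating against clinical scans requires data this package does not
ship.

## Numerical choices and degenerate inputs

* Ray tracing returns exact per-voxel chord lengths; rays missing the
  volume yield empty paths, and path sums match analytic box clipping to
  1e-6 relative.
* Division-by-zero guards: backprojection skips voxels within 1e-6 cm of
  the source plane; projections must be strictly positive before the log.
* Batch-norm uses batch statistics during training (eps 1e-5, running
  momentum 0.1) and running statistics at inference.
* The Dice of two empty masks is defined as 1.
* All stochastic steps (noise, margins, draws, initialization) consume
  explicit seeds; corpus sub-seeds are derived deterministically from the
  global seed, condition, tooth and augmentation indices.

## Known limitations

Only direct (unscattered) rays reach the detector — Compton and Rayleigh
cross sections act in attenuation only. No detector energy response, lag
or glare beyond the cutoff; no short-scan weighting or iterative
reconstruction; no beam-hardening or metal-artifact correction. The
element table and spectra are analytic approximations, flagged above. The
synthetic jaw is a fixture, not anatomy, and the package ships no
clinical data and no pretrained weights.
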
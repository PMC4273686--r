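---
title: "Phantom-based evaluation of automated PET lesion delineation: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phantom-based evaluation of automated PET lesion delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Metabolic tumour volume on FDG-PET is routinely delineated by thresholding
a volume of interest (VOI) at a fraction of the maximum standardised
uptake value (SUVmax). How well such rules recover the true volume depends
on lesion size, lesion-to-background contrast, image noise and — because
SUV-based features are resolution-dependent — on the reconstruction
protocol. `petseg` provides a fully synthetic, ground-truth-exact test
bench for this question: digital phantoms, a simplified PET image
emulator, five threshold-family delineation algorithms, a
recovery-coefficient harmonisation filter, and a validation harness.

Everything is seeded and text-reproducible; no scanner data is required.

## Phantom models

Four families are generated analytically and voxelized with a single
digitisation rule — **a voxel belongs to a shape iff its centre lies
inside the analytic surface**. The rule is deliberately simple so that an
independent brute-force per-voxel scan can verify every mask exactly
(the package's unit tests do exactly that).

* **Image-quality phantom** (`build_nema_iq_spec()`): six co-planar hot
  spheres of 10, 13, 17, 22, 28 and 37 mm diameter on the standard
  114.4-mm-diameter circle, background 5.2 kBq/ml, sphere-to-background
  contrast 4:1 or 8:1. The torso-shaped shell of the physical phantom is
  approximated by a 300-mm cylinder; the lung insert is not modelled.
* **Seven-sphere synthetic phantom** (`build_synthetic_spec("spheres")`):
  adds a 7-mm sphere; lesions placed radially (114.4 mm from the axis,
  equal angular spacing) in a 300 x 221 mm cylinder.
* **Necrotic-core phantom** (`"necrotic"`): seven 42-mm shells whose cold
  cores (background-level activity) have the seven diameters above.
* **Irregular phantom** (`"irregular"`): six seeded lesions, each a union
  of 3–7 overlapping balls with a size ladder spanning roughly the
  sphere-volume range (about 0.4–25 ml). A smooth random warp of the
  supports was considered and rejected: the plain ball unions already
  deviate strongly from spheres, and keeping the supports analytic keeps
  the voxelization oracle exact.

Exact placement and angular spacing of the radial lesions are free
choices (the package uses equal spacing at the radius that clears the
body wall for the 42-mm shells); they do not affect any metric because
each lesion is evaluated inside its own bounding VOI.

Because voxel counting is discrete, the voxelized volume of a sphere
oscillates around the analytic \((4/3)\pi r^3\) as the sphere moves by
sub-voxel offsets. Refining the grid shrinks the *expected* error (and
the surface-shell bound), but not necessarily the error of one specific
placement; the tests therefore check convergence as a mean over seeded
sub-voxel placements plus a per-sphere surface-shell bound.

## The image emulator

The real acquisition chain (forward projection, attenuation, scatter,
randoms, OSEM/TOF/PSF reconstruction) is replaced by an image-domain
emulator (`simulate_image()`):

1. trilinear resampling of the activity map onto the protocol matrix
   (ground truth is never resampled — it is re-voxelized analytically);
2. isotropic Gaussian blur at the protocol's *effective* resolution;
3. Poisson count noise: expected voxel counts are proportional to
   activity × voxel volume × total true counts; a protocol-specific
   `noise_gain` g scales relative noise (counts are drawn as
   Poisson(λ/g²)·g², with a Normal approximation above λ = 10⁶ where the
   two are indistinguishable), folding un-simulated randoms and scatter
   into a single factor;
4. the protocol's Gaussian post-filter.

Blurs are exact circular convolutions (via FFT) with a spatially
sampled, normalised Gaussian kernel. Sampling the kernel in *space*
matters: sampling the analytic transfer function in frequency instead
produces a kernel with negative ringing lobes that can overshoot the
true activity by about 1 % — enough to push recovery coefficients above
1 and break the smoothing property. With the spatial kernel the voxel
sum is conserved exactly, the maximum never increases, and cascaded
blurs add their FWHM in quadrature up to kernel-sampling error (below
1 % of the signal at these voxel sizes).

Four presets (`protocol_presets()`) emulate the ordering of clinical
reconstructions:

| preset | effective PSF FWHM | post-filter | noise gain |
|--------|--------------------|-------------|------------|
| OP     | 6.5 mm             | 5 mm        | 2.0        |
| OPTOF  | 5.5 mm             | 2 mm        | 1.5        |
| PSF    | 4.5 mm             | 2 mm        | 1.8        |
| PSFTOF | 4.0 mm             | 2 mm        | 1.4        |

The FWHM and gain values are emulation choices, not measured scanner
properties: they produce recovery-coefficient curves ordered like
clinical reconstructions (sharper protocols recover small spheres
better) and background image roughness of roughly 5–12 % at 3×10⁷ true
counts, which is the clinically typical range. The two stated count
levels are 3×10⁷ and 6×10⁷ trues; the experiment grid accepts any list
(the full-factorisation helper ships a third placeholder level at
1.5×10⁷ to complete the three-level count factor).

Default grids are 200×200 (4.073×4.073×2.027 mm voxels) and 400×400
(2.036×2.036×2.027 mm), with 64 axial slices by default; bodies longer
than the axial extent are clipped at the grid boundary. Tests and the
analysis scripts run on the 200 matrix with 32–64 slices — sizes chosen
so the whole bench runs on a laptop while every sphere, shell and
background ROI fits with margin.

## Delineation methods

All methods operate inside a bounding VOI (ground-truth bounding box
dilated by 3 voxels per axis by default) and threshold *inclusively*
(≥ T), with no connectivity filtering by default — so low thresholds
retain disconnected background voxels, reproducing the characteristic
background over-inclusion of fixed thresholding on low-contrast lesions.
A largest-connected-component option exists behind a flag.

* **T40 / T50** — T = 0.4 (or 0.5) × SUVmax(VOI).
* **AT40 / AT50** — T = f × (SUVmax − BG) + BG, where BG is the mean of a
  spherical background region of 20 voxels diameter (a ball in
  voxel-index space, hence an ellipsoid in mm on anisotropic grids)
  placed in the uniform phantom body. With BG = 0 these reduce exactly to
  T40/T50; with SUVmax ≤ BG there is no contrast and an empty mask is
  returned with a warning.
* **CT** — contrast thresholding, T = a·mSUV70 + b·BG, where mSUV70 is
  the mean over VOI voxels ≥ 0.7·SUVmax. The coefficients are calibrated
  by regression on phantom objects: for each object the *optimal*
  threshold is the one (out of 200 evenly spaced candidates between BG
  and SUVmax, ties to the lower value) whose thresholded volume best
  matches the ground truth; (a, b) then solve the no-intercept least
  squares fit. The no-intercept form follows the method's published
  structure; whether small poorly-resolved spheres should be excluded
  from the calibration is not settled, so the package pools all spheres
  and reports the fit RMSE.
* **FLAB** — listed in the method registry as *unavailable*: the fuzzy
  locally adaptive Bayesian method is an external implementation
  distributed by its authors, and this package only reserves the
  registry key and raises a clear not-implemented error.

## Harmonisation (recovery-coefficient matching)

A reconstruction-specific Gaussian filter makes protocols quantitatively
comparable before delineation: the filter FWHM minimises the RMSE between
the protocol's recovery-coefficient (RC) curve and a reference curve.
RC is measured per sphere as (max within the ground-truth mask dilated by
one voxel − background) / (true contrast); a max-based statistic is used
rather than a peak-sphere average, which makes small-sphere RC slightly
noise-optimistic but keeps the statistic monotone and simple. The
reference is the least-resolved preset (OP), mirroring harmonisation
toward a common, less-resolved target; it is configurable. The search is
a dense grid (coarse 0.5 mm, then 0.05 mm around the coarse optimum) —
the RC RMSE is smooth and unimodal in the FWHM for these curves, and the
two-stage grid keeps the fit deterministic. Filtering is never applied
before CT, whose calibration is already reconstruction-specific.

## Validation

* **SI** (similarity index): Dice overlap 2|GT∩PET|/(|GT|+|PET|); two
  empty masks score 1 (agreement on absence), and the case is flagged.
* **%VE**: signed volume error (Vol_PET − Vol_true)/Vol_true × 100.
* **CV**: SD/mean of delineated volumes across reconstructions and
  acquisitions; the sample (n−1) SD is used throughout and stated in the
  output metadata.
* **Necrotic cores**: a hot-shell delineation is scored against the shell
  directly and against the core via the cavity estimate
  fill-holes(delineation) \ delineation (3-D border-seeded flood fill,
  6-connectivity). How a core should be extracted from a hot-region
  delineation is not prescribed anywhere; hole filling is this package's
  interpretation and is stated with the results.
* Summaries report mean, SD, CV, n and the 95 % CI half-width 1.96·SD per
  group; size groups split at 17 mm (small: 10/13 mm physical, 7/10/13 mm
  synthetic; large: 17–37 mm). Distribution-style outputs are emitted as
  tidy tables, not rendered figures.

## What the bench does and does not show

The emulator reproduces, with exact ground truth, the *directional*
findings of phantom studies of SUV-threshold delineation: background-aware
thresholds (CT/AT40/AT50) clearly outperform fixed thresholds on small
low-contrast spheres; accuracy rises with sphere size for every method;
harmonisation aligns RC curves across protocols and, in the noiseless
limit, equalises delineated volumes exactly.

Two behaviours of real reconstructions are *not* reproduced, and the
package reports them honestly rather than emulating them ad hoc:

* Real OSEM/PSF/TOF reconstructions differ by convergence behaviour,
  Gibbs overshoot and attenuation/scatter residuals, which make large-
  sphere delineated volumes vary by ~20 % across protocols. In a
  Gaussian-resolution-only world the adaptive 40 % threshold is almost
  resolution-invariant for spheres ≥ 17 mm: its across-protocol volume CV
  is already below 1 % before harmonisation (at or below the voxel-
  quantisation floor), so prior filtering cannot reduce it further — the
  benefit of harmonisation for *large* lesions is a property of real
  reconstruction differences that the simplified emulator deliberately
  omits. (For small spheres the emulator's across-protocol CV is ~30 %
  and harmonisation does collapse it.)
* For the same reason the emulator's large-sphere SI baseline is ~0.99,
  leaving no headroom for filtering to improve accuracy; filtering costs
  a fraction of a percent of SI there instead of gaining.

Passing tests on this bench therefore validate the algorithms, the
metrics and the harmonisation mechanics — not the absolute SI/%VE/CV
levels of any particular scanner and reconstruction chain.

## Numerical choices

* Threshold comparison is inclusive (≥); optimal-threshold ties break to
  the lower threshold.
* The FFT blur clamps sub-machine-precision negatives to zero to keep
  volumes non-negative.
* Per-replicate seeds derive from a base seed via a fixed 32-bit mixing
  function (`task_seed()`), so any task can be replayed in isolation;
  generators save and restore the caller's RNG state.
* Degenerate inputs fail loudly: empty VOIs, flat VOIs for ground-truth
  fitting, ROIs clipped by the image bounds, all-zero backgrounds in the
  CT regression (where an a-only fit is available behind a flag),
  rank-deficient calibration designs, and unknown method or grouping
  keys all raise errors naming the problem.
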
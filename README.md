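# petseg

Phantom-based evaluation of automated PET lesion delineation.

Delineating metabolic tumour volume on FDG-PET with SUV thresholds is
standard practice, but the result depends on lesion size, contrast,
image noise and the reconstruction protocol. `petseg` is a desk-scale
test bench for that dependence, aimed at physicists and method
developers: digital phantoms with exact ground truth, a seeded
image-domain PET emulator, five threshold-family delineation
algorithms, recovery-coefficient harmonisation, and a validation
harness.

## What is implemented

**Phantoms** (`build_nema_iq_spec()`, `build_synthetic_spec()`): the
six-sphere image-quality phantom (10–37 mm, background 5.2 kBq/ml,
contrast 4:1 / 8:1), a seven-sphere variant (adds 7 mm), 42-mm shells
with cold necrotic cores, and seeded irregular lesions; all voxelized by
a centre-inclusion rule with exact per-lesion ground-truth masks.

**Emulator** (`simulate_image()`): Gaussian blur at the protocol's
effective resolution, Poisson count noise scaled to the acquisition's
true-count level, and the protocol post-filter; four presets (OP,
OP+TOF, PSF, PSF+TOF) ordered like clinical reconstructions; seeded,
replicable.

**Delineation** (`delineate()` and friends):

| key | rule |
|-----|------|
| T40 / T50 | T = 0.4 (0.5) × SUVmax |
| AT40 / AT50 | T = 0.4 (0.5) × (SUVmax − BG) + BG |
| CT | T = a·mSUV70 + b·BG, (a, b) calibrated by volume-matching regression on phantom spheres |
| FLAB | registry stub — external method, reported as unavailable |

BG is the mean of a 20-voxel-diameter spherical background region;
mSUV70 is the mean over VOI voxels ≥ 0.7·SUVmax.

**Harmonisation** (`fit_eqpet_filter()`, `apply_eqpet()`): per-protocol
Gaussian filter sized by minimising the RMSE between the protocol's
recovery-coefficient curve and a reference curve, applied before
delineation (never before CT).

**Validation** (`similarity_index()`, `percent_volume_error()`,
`coefficient_of_variation()`, `evaluate_necrotic()`,
`summarise_records()`): Dice overlap SI = 2|GT∩PET|/(|GT|+|PET|), signed
%VE = (Vol_PET − Vol_true)/Vol_true × 100, CV = SD/mean of volumes
across reconstructions, shell/core scoring via cavity extraction, and
grouped summary tables with 95 % CI half-widths (1.96·SD).

**Harness** (`experiment_grid()`, `run_experiment()`): expands a factor
grid (lesions × contrasts × protocols × counts × replicates × matrices
— the full study factorisation is 2,880 objects), runs simulate →
(optional harmonisation) → delineate → validate, and writes tidy CSV/JSON
results.

## Worked example

```r
library(petseg)

spec <- build_nema_iq_spec(contrast = 8)      # six spheres, 8:1, 5.2 kBq/ml
vox  <- voxelize(spec)                        # activity map + exact GT masks
img  <- simulate_image(vox$activity, protocol_presets()$OP,
                       acquisition_config(6e7, replicates = 10, base_seed = 42),
                       replicate_index = 1)
bg   <- measure_background(img, world_to_index(img, spec$bg_roi_center))

gt  <- vox$masks$sphere37mm
voi <- bbox_from_mask(gt, margin = 3)
for (m in c("T40", "AT40", "AT50")) {
  r <- delineate(img, voi, m, bg = bg)
  cat(sprintf("%-4s SI %.3f  %%VE %+.1f\n", m,
              similarity_index(gt, r$mask),
              percent_volume_error(mask_volume_ml(r$mask), mask_volume_ml(gt))))
}
recovery_coefficient_curve(img, vox$masks, 41.6, 5.2, "OP")
```

```
T40  SI 0.944  %VE +11.9
AT40 SI 0.994  %VE -0.4
AT50 SI 0.933  %VE -12.6
<recovery_curve> OP
 10mm  13mm  17mm  22mm  28mm  37mm 
0.416 0.584 0.852 0.961 1.010 1.055
```

The fixed 40 % threshold over-segments the 37-mm sphere (+12 % volume)
because it ignores the background plateau; the background-adaptive
threshold lands on the true edge (−0.4 %). The recovery curve shows the
partial-volume effect the harmonisation filter works on: the 10-mm
sphere recovers only ~42 % of its true contrast under this preset (the
max-based RC of fully recovered spheres sits slightly above 1 through
noise).

The numbered scripts under `analysis/` run the full workflow — phantom
construction, CT calibration, harmonisation-filter fitting, the reduced
experiment grid, and the necrotic-core evaluation — writing tables under
`results/` (and NIfTI images under `scratch/`):

```sh
Rscript analysis/01_build_phantoms.R
Rscript analysis/02_calibrate_ct.R
Rscript analysis/03_fit_eqpet.R
Rscript analysis/04_run_reduced_grid.R
Rscript analysis/05_necrotic_and_summaries.R
```

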
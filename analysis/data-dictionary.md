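# Data dictionary

## Validation records (`results/reduced_grid/*, run_experiment()` output)

One row per delineated object-condition (and per filtering state).

| column | type | meaning |
|--------|------|---------|
| `si` | numeric [0,1] | similarity index (Dice overlap) of delineation vs ground truth; 1 = perfect. NA for unavailable methods |
| `pct_ve` | numeric >= -100 | signed percentage volume error, (Vol_PET - Vol_true)/Vol_true x 100; -100 = empty delineation |
| `vol_pet` | ml | delineated volume |
| `vol_true` | ml | ground-truth mask volume |
| `method` | chr | delineation key: T40, T50, CT, AT40, AT50, FLAB |
| `protocol` | chr | reconstruction preset: OP, OPTOF, PSF, PSFTOF |
| `counts` | numeric | true coincidence events of the emulated acquisition |
| `contrast` | numeric | lesion-to-background activity ratio |
| `replicate` | int | replicate index within the condition |
| `matrix` | chr | grid label (e.g. "200" = 200x200, 4.073 mm in-plane) |
| `lesion` | chr | lesion id within the phantom |
| `diameter_mm` | mm | sphere (or shell outer) diameter; NA for irregular lesions |
| `size_group` | chr | "small" (< 17 mm) or "large" (>= 17 mm) |
| `eqpet` | chr | "off" / "on": harmonising filter applied before delineation (never "on" for CT) |
| `status` | chr | "ok" or "unavailable" (FLAB stub) |
| `note` | chr | captured warnings (empty mask, SUVmax <= background, ...) |

Necrotic records (`results/necrotic/`) add `component` ("shell" = scored
against the hot outer layer; "core" = cavity estimate scored against the
cold core) and `core_mm` (core diameter).

## Summary tables (`summarise_records()`, `results/tables/`)

Per group: `mean`, `sd` (sample SD, n-1), `cv` (= sd/mean when mean > 0),
`n`, `ci95_halfwidth` (= 1.96 x sd), plus the grouping columns.

`volume_cv_by_lesion.csv`: coefficient of variation of `vol_pet` across
reconstruction protocols and replicates, one row per (method, lesion,
contrast, matrix, counts, eqpet); `volume_cv_summary.csv` averages those
CVs per (method, size_group, eqpet). `si_quartiles.csv` gives the
distribution (q25/median/q75/mean) of SI per method, sphere size and
filtering state — the tabular analogue of the usual box plots.
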
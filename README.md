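# osteoct

Density-tiered micro-CT morphometry of maturing cortical bone.

In a growing long bone, trabecular struts in the metaphysis coalesce into a
cortical shell that then densifies. While that is happening, "trabecular
versus cortical" is not a well-posed distinction, so analyses that depend on
drawing it by hand break down exactly where cortical maturation happens.
`osteoct` is for skeletal biologists and micro-CT core facilities who want
an *objective* readout of that process: it segments calibrated scans into
mineral-density tiers with unsupervised multi-level Otsu thresholding and
reports the composition of the whole metaphyseal cross-section, plus 3D
cortical porosity with per-pore morphometry.

## What it computes

* **Calibration** — affine grayscale → mineral density (g/cm³ calcium
  hydroxyapatite) by OLS through phantom-insert measurements.
* **Tier boundaries** — 4-level Otsu thresholds maximising between-class
  variance σ²_B(t₁,t₂,t₃) = Σₖ ωₖ(μₖ − μ)², solved exactly by dynamic
  programming, derived per sample over a reference cohort and averaged;
  consistency reported as 100·(max−min)/midpoint. Reference tier floors:
  low 0.632, mid 1.143, high 1.528 g/cm³ CaHA; the quartile below 0.632 is
  excluded from tier analysis.
* **ROI placement** — regions as fractions of bone length from the
  growth-plate slice (metaphysis: offset 7.5%, length 15%; diaphysis:
  offset 30%).
* **Profiling** — per-tier bone volume as a fraction of total metaphyseal
  (filled-envelope) volume, whole-ROI and per 9 µm slice.
* **Porosity** — bone at a global 0.238 g/cm³ threshold; pores as
  6-connected cavities in the filled envelope; open/closed status (open =
  reaches the region's top/bottom slice or the outside), volume, marching-
  tetrahedra iso-surface area and SA:V per pore.
* **Group statistics** — repeated-measures two-way ANOVA with
  Šidák-adjusted per-tier contrasts, and slice-onset detection along the
  metaphysis.
* **Synthetic phantoms** — metaphysis-like volumes (cortical shell, marrow,
  struts, axial mineralisation gradient, embedded pores, calibration
  inserts, point-spread blur, noise) with exact voxel-level ground truth,
  so the whole pipeline is testable without scanner data.

## Worked example

A full pass over a synthetic metaphysis phantom — calibrate from its
inserts, derive tier thresholds from a 3-scan cohort, classify, profile,
and measure porosity:

```r
library(osteoct)

spec   <- phantom_preset("gradient", seed = 2)
ph     <- generate_phantom(spec)
cur    <- fit_calibration(measure_inserts(ph$volume, spec))
print(cur)
#> <calibration_curve> density = 0.010291 * gray + -0.00275018  (r^2 = 1.0000, 2 points)

cohort <- generate_reference_cohort(spec, n = 3, gray_shift_sd = 2, seed = 2)
tiers  <- derive_reference_thresholds(lapply(cohort, `[[`, "volume"),
                                      roi = ph$truth$roi, calibration = cur)
print(tiers)
#> <density_tiers> excluded < 0.460344 | low [0.460344, 1.11211) | mid [1.11211, 1.64724) | high >= 1.64724  (g/cm^3 CaHA)
#>   cohort n = 3; per-threshold spread % : 8.89, 4.61, 3.12

labels <- classify_voxels(gray_to_density(ph$volume, cur), tiers)
print(roi_summary(labels, roi = ph$truth$roi))
#> <roi_summary> ROI volume 2.42e+08 um^3 | low 35.84% mid 21.76% high 7.70% (bone 65.29%)

res <- measure_porosity(gray_to_density(ph$volume, cur), roi = ph$truth$roi)
print(res$report)
#> <porosity_report> porosity 30.306% (open 30.306%, closed 0.000%) | 3 pores (2 open, 1 closed)
```

Reading the output: the calibration line recovered the phantom's designed
density map (0.01 g/cm³ per gray unit); the cohort-derived tier floors land
in the gaps between the phantom's density modes, with a few percent spread
across samples; the ROI is 65% bone by volume, mostly low/mid density as
expected near the growth plate; and porosity is dominated by the open
marrow cavity (in this phantom the compartment includes the marrow — the
two "open" pores are the marrow space and a transcortical channel, the
closed one an embedded cavity). Ground truth for every one of these numbers
is in `ph$truth`.

The same pipeline is scriptable from a shell via the thin wrapper in
`exec/osteoct` (`simulate`, `calibrate`, `thresholds`, `classify`,
`profile`, `porosity`, `compare`, `report`).

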
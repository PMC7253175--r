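---
title: "Density-tiered morphometry of maturing cortical bone"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Density-tiered morphometry of maturing cortical bone}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(osteoct)
```

## The problem

In the metaphysis of a growing long bone, trabecular struts coalesce into a
cortical shell which then densifies. During this transition the usual
dichotomy of "trabecular" versus "cortical" bone is ill-defined, so any
analysis that requires drawing that boundary by hand is subjective precisely
where the biology is most interesting. `osteoct` instead quantifies the
*mineral-density composition* of the whole metaphyseal cross-section: bone
voxels are segmented into low-, mid- and high-density tiers on the calcium
hydroxyapatite (CaHA) scale, and each tier is reported as a fraction of the
total metaphyseal volume, whole-region and slice-by-slice from the growth
plate toward the diaphysis. Alongside it, the package measures 3D cortical
porosity with a per-pore inventory (volume, iso-surface area, SA:V,
open/closed status).

Because no voxel-level scan data are deposited for this kind of study, the
package carries a first-class synthetic phantom generator with exact voxel
ground truth; every pipeline stage is validated against phantoms and
analytic oracles rather than against irreproducible scans.

## The segmentation model

Voxel grayscale is mapped to mineral density by an affine calibration fitted
by ordinary least squares to phantom inserts of known CaHA density
(`fit_calibration()`); this is the standard micro-CT protocol, and a single
affine map per scan configuration is assumed (no beam-hardening or per-slice
drift correction).

Tier boundaries are derived, not chosen: 4-level Otsu thresholding is run on
the region-of-interest grayscale histogram of each sample of a reference
cohort (`derive_reference_thresholds()`). Multi-level Otsu picks the
strictly increasing threshold tuple that maximises the between-class
variance of the histogram; `multi_otsu()` solves this *exactly* by dynamic
programming over cumulative zeroth/first moments, with ties broken toward
the lexicographically smallest tuple. Exactness is the contract: the test
suite and the acceptance script both compare it against brute-force
enumeration of every threshold tuple on histograms of up to 64 bins.
Thresholds are lower-inclusive class floors (a voxel exactly at a boundary
belongs to the tier above), reported as the lower edge of the class's first
bin. Histograms use the native 256 unit bins for 8-bit data and 256
equal-width bins over the observed range otherwise; this matches vendor
behaviour on 8-bit reconstructions without inventing precision.

The cohort consensus is the arithmetic mean of per-sample thresholds
(a pooled-histogram mode is available via `mode = "pooled"`); per-sample
values are kept for audit, and their consistency is reported as
`percent_spread()` — range over midpoint, the convention that reproduces the
published consistency figures (11%, 5%, 3.5%) from the published per-sample
ranges. The reference tier floors are 0.632 / 1.143 / 1.528 g/cm³ CaHA
(`density_tiers()`), with an archive-scan variant 0.565 / 1.036 / 1.432
(`archive_tiers()`). Everything below the lowest floor is "excluded":
partially mineralised tissue and background, deliberately left out of the
tier analysis.

## Regions and envelopes

Regions of interest are placed as fractions of bone length from a
user-supplied growth-plate reference slice (`select_roi()`): metaphysis =
offset 7.5%, length 15%; diaphysis = offset 30%. The landmark is
user-supplied by design — the original protocol places it manually, and
inventing an automatic detector would add an undocumented degree of
freedom. Micrometre-to-slice conversion rounds half-away-from-zero
(documented because the protocol's own rounding is unstated; the resulting
slice count is always within one voxel of the nominal fraction).

"Total cross-sectional area" is the filled periosteal envelope
(`cross_section_mask()`): bone plus every cavity fully enclosed by bone in
2D, computed by flood-filling the background from the slice border.
Including the marrow cavity makes tier fractions comparable between porous
and consolidated cortices. Two envelopes coexist deliberately:

* tier profiling (`slice_profile()`, `roi_summary()`) defaults to the
  envelope of the *tier-classified* bone (density ≥ lowest tier floor);
* porosity uses the envelope of the *global-threshold* bone
  (density ≥ 0.238 g/cm³).

Each analysis's denominator is derived from its own bone definition, so a
threshold change never silently changes the other analysis. Both functions
accept an explicit `envelope` argument to override this.

Slices with zero cross-sectional area propagate `NA` percentages (flagged in
the output) rather than zeros, which would bias group means.

## Porosity and pore morphometry

Bone is `density >= 0.238 g/cm³` (lower-inclusive, `bone_mask()`). The
compartment is the stacked filled envelope; pore voxels are compartment
minus bone. Pores are 6-connected components (bone implicitly 26-connected —
complementary connectivities avoid topological paradoxes in 3D binary
images). A pore is **open** if it reaches the first or last slice of the
measurement region or touches (6-adjacency) any voxel outside the
compartment; otherwise **closed**. Open plus closed volume equals total pore
volume exactly, by construction, and the suite asserts it on every phantom.

Per-pore surface area is reported two ways. The voxel-face count is exact
for the digitised shape but overestimates smooth surfaces by roughly 1.5×,
so SA:V uses an iso-surface mesh instead: marching tetrahedra at level 0.5
on the component smoothed with a Gaussian of σ = 0.8 voxel. The smoothing
constant was fixed against the analytic sphere oracle during design: an
unsmoothed binary mesh overestimates a sphere's area by ~9% (marching
tetrahedra by ~28%), σ = 0.8 brings it within 1%. Components so small that
smoothing leaves nothing above the level are meshed unsmoothed — their area
is then a voxel-scale overestimate, which is acceptable because such pores
(one to a few voxels) sit at the detection floor anyway and are flagged
`at_limit` (default floor 5,000 µm³ at 9 µm voxels) rather than dropped.

## The phantom generator

`phantom_spec()` describes a metaphysis-like object: an elliptical cortical
shell (optionally around a marrow cavity bridged by axial trabecular
struts), an axial mineralisation gradient, embedded pores, calibration
inserts outside the bone, then a Gaussian point-spread blur and additive
Gaussian noise with clipping to the representable grayscale range. Ground
truth — per-slice tier fractions, ROI fractions, pore inventory with
open/closed flags, porosity — is captured on the label volume *before* blur
and noise, by exact voxel counting. The geometry seed (`strut_seed`) is
separate from the noise seed, so truth is invariant to the noise
realisation by construction.

The axial gradient is expressed as per-tier weights as a function of the
axial fraction; within a slice, bone voxels are assigned to tiers by angular
sector in proportion to the weights. This keeps the per-slice tier fractions
exact, deterministic and monotone when the weights are monotone — emulating
the biology (bone more mineralised with distance from the growth plate)
without simulating remodelling.

Two phantom features deserve justification:

* **Graded surface and pore linings.** Real forming surfaces (periosteal,
  endosteal, pore walls) are lined by newly deposited, lowly mineralised
  bone; mineral density ramps up over tens of micrometres. The phantom
  reproduces this with a low-tier band at every surface and a capped-at-mid
  band behind it (27 µm each by default). Besides realism, this has a
  numerical consequence: every material interface is a one-tier step, so
  after point-spread blur the classification threshold between two adjacent
  tiers sits near the midpoint of each edge and partial-volume
  misclassification stays near zero-mean. An abrupt air-to-high-density
  interface, by contrast, puts thresholds far off the edge midpoint and
  biases every boundary voxel the same way.
* **Pore sizes in the recovery preset.** At the 0.238 g/cm³ global
  threshold, blur inherently erodes a pore boundary by ~0.6 voxel of radius
  (the threshold lies below the pore-edge midpoint). Porosity recovery to
  fractions of a percentage point is therefore only meaningful for pores
  whose radius is large against the point spread; the recovery preset uses
  two closed pores of radius 315 and 72 µm giving ~5% true porosity of the
  metaphyseal region.

Defaults: 9 µm voxels, 8-bit grayscale, tier gray means 0/90/135/200 placed
on the calibration line density = 0.01 × gray (so insert-derived calibration
recovers the designed densities), psf σ = 1 voxel, noise sd = 3 gray —
i.e. tier-mean separation over noise of at least 10, a regime comparable to
a good laboratory reconstruction. The scans behind the original protocol do
not document their noise level or bit depth, so these are free parameters of
the phantom, not estimates of any particular scanner.

What the phantom does *not* emulate: beam hardening, ring artefacts,
scatter, detector blooming, cartilage and the growth plate itself, or
realistic trabecular network topology (struts are axial cylinders). Passing
recovery tests on phantoms therefore demonstrates correctness of the
measurement pipeline under partial volume and noise — not robustness to
scanner artefacts.

A documented limitation follows from partial volume: structures thinner than
a few voxels (the gradient preset's 13.5 µm struts) blur toward the
background and are systematically classified a tier lower than their true
mineral class. This is a property of the imaging model, shared with real
scans at equivalent resolution, and is why the quantitative recovery
criteria are evaluated on the consolidated (`"recovery"`) preset while the
marrow-and-struts (`"gradient"`) preset exercises the end-to-end path.

## Group statistics

`compare_tier_fractions()` fits the split-plot two-factor model (group
between samples, tier repeated within sample) with `stats::aov` and
extracts per-tier group contrasts via estimated marginal means, adjusted by
the Šidák closed form `1 − (1 − p)^m` over the tier family.
`slice_onset()` reproduces the slice-arrow presentation: each slice's tier
fraction is contrasted against the baseline slice at one end of the region
(paired t within a group; Welch t between groups — both modes are provided
because the published legend is ambiguous about which contrast the arrows
derive from), Šidák-adjusted over the tested slices; the onset is where
significance begins. Missing slice values are dropped pairwise with their
reduced n recorded. The t statistics are computed vectorised over slices
(standard formulas, `stats::pt`), which keeps Monte-Carlo calibration of
the procedure cheap; the suite verifies type-I control (≥ 94% of label
permutations of identical data yield no significant contrast at α = 0.05)
and power (a 10 pp shift at sd 2 pp, n = 9, detected in ≥ 95% of
replicates).

## Numerical choices, in one place

* Otsu DP vs exhaustive search: exact equality asserted, ties broken to the
  lexicographically smallest tuple; adding empty bins or rescaling counts
  never moves thresholds.
* All classification boundaries are lower-inclusive (`>=`).
* Slice rounding: half-away-from-zero.
* Pore connectivity 6, bone 26; mesh level 0.5, mesh smoothing σ 0.8 voxel
  with unsmoothed fallback.
* roi_summary equals the cross-section-weighted mean of slice_profile to
  1e-12 relative — asserted, since the two are computed independently.
* Degenerate inputs error loudly: empty histograms, duplicate calibration
  points, negative calibration slope, grayscale volumes where density is
  required, empty bone masks, single-sample groups.

## Problem sizes used by the tests

The suite validates recovery on one 200 × 200 × 300-voxel phantom (the
`"recovery"` preset), runs the Otsu oracle on 100 histograms of up to 64
bins, and calibrates the statistics on 200 Monte-Carlo replicates per rate;
these sizes give stable rates while keeping a full run of suite plus
acceptance script in single-digit minutes on one core.
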
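---
title: "Haematoma volumetry on CT: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Haematoma volumetry on CT: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ichvol)
```

## The problem

Intracerebral haemorrhage (ICH) volume on CT predicts outcome and steers
treatment decisions, yet it is measured in several inequivalent ways:

* **ABC/2** — the bedside ellipsoid approximation: the longest axial
  diameter *A*, its in-plane perpendicular *B* on the same slice, and the
  craniocaudal extent *C* (slice thickness summed over slices showing
  blood), combined as *A·B·C/2*. For a true ellipsoid this returns
  3/π ≈ 0.955 of the exact volume π/6·*A·B·C*.
* **Modified ABC/2** — the same formula, but each slice contributes to *C*
  with weight 0 if its haemorrhage area is below 25% of the largest
  slice's area, 0.5 between 25% and 75% (boundaries inclusive), and 1
  above 75%.
* **SAS** (semiautomated segmentation) — planimetry: voxels inside a
  Hounsfield-unit (HU) window, restricted to one connected component,
  optionally hand-edited; per-slice areas are summed weighted by slice
  thickness.
* **AVC** (automatic volume calculation) — seed-based 3D region growing
  in the same window over the whole series; it refuses scans whose slice
  thickness varies, as the clinical tooling it models does.

Because no public ICH imaging series with voxel-level ground truth exists,
the package evaluates these estimators on **synthetic CT phantoms** whose
true volumes are known analytically, and supplies the statistics used for
method comparison: intraclass correlation coefficients (ICC),
Bland–Altman analysis with difference-vs-mean regression, paired tests
and rank correlation. Intraventricular haemorrhage (IVH) is scored with
the classic Graeb and modified Graeb ordinal scales.

## The phantom model

A lesion is the union of a core ellipsoid (diameters `diameters_mm`,
in-plane rotation) and `n_lobes` satellite ellipsoids whose centres sit at
`lobe_depth` times the distance from the core centre to its surface,
with diameters `lobe_scale` times the core's. This gives a single
irregularity knob with a computable oracle volume: `n_lobes = 0` is a
regular lesion, two or more lobes give ground-truth class *irregular*.

Rendering uses **partial-volume mixing**: each voxel's HU is
`occ · (mean_hu + h) + (1 − occ) · background_hu`, where the occupancy
`occ` is the fraction of 4×4×4 sub-voxel sample points inside the
analytic shape and `h` is a spatially smoothed (separable Gaussian,
σ ≈ 1.2 voxels) heterogeneity field rescaled to SD `hetero_sd_hu` over
lesion voxels. Global acquisition noise (`noise_sd_hu`) is added
everywhere. The **oracle volume** is the 4× supersampled voxelisation of
the analytic shape — the same indicator evaluations, so it is exact to
about 0.1% for desk-scale lesions and independent of any segmentation.
The ground-truth mask (occupancy ≥ 0.5) is returned alongside.

Default tissue values — background 30 HU, lesion mean 65 HU, noise SD
4 HU, heterogeneity SD 0–15 HU — keep lesions inside the 40–80 HU window
typical of acute blood on brain.

### What the generator emulates, and what it does not

The default cohort reproduces the statistical structure of a large acute
ICH series: visual size categories `<3 / 3–4.9 / 5–8 / >8` cm in
proportions 0.41/0.41/0.16/0.02; irregular shapes more likely in larger
categories (0.50/0.70/0.85/0.95, about 64% irregular overall); axis
ratios 0.6–0.9; 1 mm in-plane spacing with 4 mm slices; and a random
sub-voxel alignment of each lesion with the slice grid, as in real
acquisitions. Lobes are mostly embedded (`lobe_depth = 0.75`) so
irregularity reads as marginal undulation rather than separate satellite
balls; strongly protruding lobes would inflate the measured diameters far
faster than the volume, which contradicts the consistent observation in
clinical series that ABC/2 and planimetry agree on average. A
variable-thickness preset (4 mm slices below a configurable level, 8 mm
above) reproduces the acquisition style that defeats seed-grown AVC.

Not emulated: the skull and bone artefacts, CT reconstruction physics,
perihaematomal oedema, voxel-wise ventricular anatomy (ventricular blood
is modelled parametrically for the scoring scales, below), and human
visual adjudication (phantom ground-truth classes stand in for the 1–5
visual shape/density ratings). Passing tests therefore demonstrate
estimator correctness and directional behaviour under controlled
conditions, not clinical performance on real scans.

## Numerical choices in the measurement layer

**Threshold window.** In practice the window is established by sampling
the haemorrhage and normal brain. On partial-volume-blurred data the
threshold position matters: a bound at HU level *L* cuts the occupancy
ramp at `(L − background) / (mean − background)`. The package's
`midpoint_window()` places the lower bound midway between background and
lesion mean, cutting the ramp at occupancy 0.5, which makes the
thresholded surface unbiased. A clinically-styled 40–80 HU window on the
default tissues cuts at occupancy 0.29 and dilates the mask by ~0.2 mm
on every face — about +6% volume on a 20 mm sphere, shrinking with
lesion size; the tests assert exactly this behaviour. The upper bound
defaults high for phantom work because there are no bright confounds
(bone, calcified choroid) to exclude. Slice-wise hole filling
(`fill_holes = TRUE`) stands in for the manual boundary editing used
when heterogeneous lesions drop interior voxels below the window.

**Connectivity.** Components are 26-connected in 3D (8 in-plane) by
default — the most inclusive choice, matching visual contiguity; 6 and 18
are available.

**Diameters.** A and B are measured on the sub-voxel boundary contour
(marching squares at the 0.5 level of the antialiased slice; thin regions
fall back to the raw binary contour, so a single voxel has extent one
spacing). Two cruder conventions were rejected because each carries a
systematic bias that the rendered-ellipsoid oracle exposes: pairwise
distances between boundary-voxel centres truncate half a voxel at each
end and, worse, pick up oblique staircase-corner chords that exceed the
true axis; adding one spacing (the count-based convention) then
over-corrects blunt tips. The antialiased contour measures an
axis-aligned rendered ellipse's axes to within a fraction of a voxel, the
way a human aligns calipers with the apparent axis. Ties for the
A-carrying slice break toward the lower slice index.

**C.** Summed per-slice thickness over slices showing any blood — the
faithful generalisation of "thickness × number of slices" to
variable-thickness scans. The modified-ABC/2 weights treat areas at
exactly 25% and 75% of the maximum as 0.5 (the boundary readings of the
printed rule), with a small epsilon guarding float comparison.

**Size categories.** Bins are `[0,3)`, `[3,5)`, `[5,8]`, `(8,∞)` cm on
the longest diameter in any plane; 5.0 falls in `5–8` because the printed
categories `3–4.9` and `5–8` are adjacent and exhaustive.

**Morphometry.** The largest-area slice (ties toward the lower index)
yields area, perimeter, and the mean/SD of lesion attenuation. The
perimeter is the marching-squares contour length of the antialiased
slice: contouring the raw binary mask overestimates a disc's perimeter by
~7% (staircase inflation), while boundary-voxel counting is ~27% high.
The shape index is circularity `P / (2·sqrt(π·A))` — dimensionless, 1 for
a disc, consistent with cohort means near 1.2 reported for real
haematomas; the squared form `P²/(4πA)` is available as a swappable
strategy. The density index is the coefficient of variation
`sd_hu / mean_hu`.

## IVH scoring schemas are data

`graeb_schema()` loads YAML schema files; two ship with the package. The
classic Graeb scale scores the lateral ventricles 1 (trace) to 4 (full
and expanded) and the third/fourth ventricles 1 (blood present) or 2
(filled and expanded), maximum 12. The modified scale's prose — per-
compartment quartile scores plus an expansion point per ventricle — can
only reach its printed maximum of 32 if eight compartments (paired
frontal-horn-plus-body, temporal and occipital horns, third, fourth) are
scored 0–4 with the expansion bonus **off**; the default schema honours
the printed maximum and exposes the bonus as `expansion_bonus = 1`, which
raises the attainable maximum to 36. `schema_max()` computes the maximum
by scoring the maximal state rather than trusting a stored constant.
"Trace" is a flag, not an epsilon fill, because the classic scale
distinguishes it from fraction-based levels. States described on the
finer 8-compartment layout are aggregated per ventricle (mean fill, any
trace, any expansion) when scored against the classic schema.

## Agreement statistics

`icc()` computes single-measurement ICCs from the two-way mean squares.
The default form is two-way random effects, absolute agreement —
observers are interchangeable raters measuring the same scans — with
two-way mixed, consistency available for sensitivity; every result
carries its model label because the two answer different questions.
Missing cells are an error (no imputation). `bland_altman()` reports the
mean difference, 1.96·SD limits of agreement, and the OLS regression of
difference on pairwise mean whose slope captures proportional bias; with
`x` the modified method and `y` the reference, an underestimate that
grows with size yields a negative slope. Paired method differences use a
paired *t* test by default (the comparison the reported p-values imply),
Wilcoxon as an option; differences that are constant to rounding report
the machine floor rather than failing. No multiple-testing correction is
applied, matching the conventional per-comparison 0.05 level.

## The observer model

Human variation is modelled with three components: multiplicative
log-normal error on A and B (`diameter_error_sd`), random exclusion of
slices holding under 10% of the maximum slice area (`slice_flip_prob`),
and uniform jitter of the window bounds (`threshold_jitter_hu`). A
zero-noise model reproduces the direct measurement bit-exactly (same code
path, identity perturbations). The defaults (0.03 / 0.05 / 1.5 HU) are
tuned only so simulated intra- and interobserver ICCs land in the ranges
reported for trained observers; they are not estimates of any particular
reader, and phantom ICCs run higher than human ones because the phantom
task is easier. Sessions are independent draws with the same parameters,
mirroring blinded repeat readings weeks apart.

## Problem sizes and determinism

Desk-scale defaults keep a full study run in tens of seconds: 100
phantoms, 2 observers × 2 sessions, 1 mm in-plane / 4 mm slices. Every
stochastic element — lobe directions, heterogeneity, noise, cohort draws,
observer perturbations — derives from explicit seeds, and identical
(config, seed) pairs give bit-identical phantoms, manifests and reports.
`n`, the grid resolution and the mixtures all scale through
`cohort_config()` and `study_config()`.

## Known limitations

* Ellipsoid-union lesions cannot represent concave or fingering
  morphologies (e.g. lobar bleeds dissecting along white-matter tracts);
  the shape index range they span is narrower than in clinical series.
* The density-class (1–5) surrogate is an uncalibrated monotone map of
  the heterogeneity CV, not anchored to published visual ratings.
* SAS and AVC share the segmentation machinery, so their agreement on
  uniform scans is structural rather than evidence of independence.
* IVH is scored from parametric fill states; no voxel-wise ventricular
  blood is rendered, and IVH volume by planimetry is supported only for
  externally supplied masks.
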
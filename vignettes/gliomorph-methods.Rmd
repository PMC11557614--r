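---
title: "Tumor morphometry and prognostic modelling: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Tumor morphometry and prognostic modelling: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gliomorph)
```

## What the package models

Glioblastoma infiltrates at its margins, so the geometry of the
tumor--brain interface may carry prognostic information beyond plain
volume. From a 3D binary segmentation mask with anisotropic voxel spacing,
`gliomorph` computes:

* **Volume** $V$ (mL): foreground voxel count times voxel volume.
* **Total surface area** (TSA, cm²): area of the triangulated boundary.
* **Contact surface area** (CSA, cm²): TSA minus the dura-adjacent part of
  the surface, i.e. the interface with brain parenchyma.
* **Sphericity index** $SI = \mathrm{TSA} / \big(\pi^{1/3}(6V)^{2/3}\big)$:
  TSA over the surface area of the equal-volume sphere; 1 for a ball,
  larger for irregular shapes.
* **Area-to-volume ratio** $A/V$ (cm⁻¹).
* **Extent of resection** $\mathrm{EOR} = 100\,(V_{pre}-V_{post})/V_{pre}$,
  with GTR defined as exactly 100% (postoperative residue below one voxel
  volume counts as zero).

The measures feed a survival pipeline: nonparametric screens
(Shapiro--Wilk, Mann--Whitney, Kruskal--Wallis, Spearman), univariable Cox
models per measure, and two multivariable Cox models (a "CSA model" and an
"SI model"), each adjusting for preoperative volume, MGMT promoter
methylation, age, postoperative KPS and EOR, compared by Harrell's C-index
and AIC.

## Surface-area estimation

Surface area from binarized voxel data is the one numerically delicate
step. Two obvious estimators fail:

* voxel-face counting overestimates smooth surfaces by up to ~50%;
* marching cubes applied directly to the 0/1 grid places every vertex at
  an edge midpoint and produces a staircase whose area overestimates a
  digitized sphere by a *non-vanishing* ~8.6% at every resolution.

`extract_mesh()` therefore uses a **surface-nets** extraction (one vertex
per sign-changing grid cell at the mean of its edge crossings, one quad
per crossing lattice edge), followed by **Taubin smoothing with a
half-voxel clamp**: a shrink-free $\lambda|\mu$ relaxation
($\lambda = 0.6$, $\mu = -0.64$, 100 iterations) in which no vertex may
move more than `band` = 0.3 voxels from its raw position. This is the
constrained-smoothing strategy of modern label-map-to-surface tools. Its
properties, all verified by the test suite against closed forms:

* the mesh is watertight by construction (surface nets have no ambiguous
  configurations, unlike table-based marching cubes on binary data);
* flat faces stay flat: a 20 mm cube at 0.5 mm spacing keeps its area to
  within 2%, so its SI lands within 2% of the analytic
  $(6/\pi)^{1/3} \approx 1.2407$;
* the staircase residual is bounded by the clamp, so the error scales with
  voxel size: the digitized-ball SI error decreases strictly as spacing
  halves over 1.0 → 0.5 → 0.25 mm (the exact values are recomputed by
  `scripts/acceptance.R`).

An optional Gaussian pre-smoothing of the grid (`gaussian_sigma_vox`)
exists but defaults to off; with the clamped relaxation it is not needed
for accuracy. Volume is *never* taken from the mesh: voxel count times
voxel volume is exact for the digitized object (a 20 mm cube at 0.5 mm
spacing gives exactly 8.000 mL).

We considered extracting the isosurface from the raw binary grid with no
smoothing at all, for maximal reproducibility. It is not a viable default:
the ~8.6% staircase bias would propagate into SI (a pure-shape measure)
and never converge, so the constrained smoothing is part of the estimator,
not cosmetics.

## The dural-contact surrogate

In the clinical workflow the dura-adjacent surface is segmented manually.
The package automates a surrogate: `label_contact()` marks a face as
dura-adjacent when its centroid lies within `tolerance_mm` (default
1.0 mm) of the brain-mask exterior. Two consequences worth knowing:

* The tolerance adds a rim zone around a flush contact patch. For a ball
  of radius $R$ truncated at its equator and flush against a planar
  boundary, the contact area is the flat disc $\pi R^2$ *plus* a spherical
  zone of area $2\pi R \tau$ (independent of latitude), so the measured
  dural fraction at $R = 20$, $\tau = 1$ is $\approx 0.36$ rather than
  exactly $1/3$. Tests use this closed form as the oracle.
* The brain boundary is a *dura surrogate*: how far from the dura counted
  as "adjacent" in the manual workflow is not knowable from the
  measurements themselves, so 1.0 mm is a declared default, not a
  reproduction.

To reproduce a manual workflow exactly, `label_contact_voxels()` accepts a
per-voxel label map (value 2 on dura-adjacent tumor voxels, read with
`read_mask(..., binarize = FALSE)`).

## Inclusion rules and I/O

Multifocality — tumor segments separated by a gap of one or more
background voxels — excludes a case. The default adjacency is the
26-neighbourhood (`"face-edge-vertex"`): a "gap" criterion implies that
diagonal contact does not split a tumor; 6-connectivity is available as a
config option since the convention is not universal. Empty masks are legal
at the I/O layer (readers stay total) and are rejected only by
morphometry; `validate_unifocal()` returns an exclusion *flag* rather than
raising, so pipelines can log and drop cases the way an inclusion
flowchart does.

Volumes are read and written as single-file NIfTI-1 (`.nii`/`.nii.gz`).
Because no NIfTI reader is available in the supported dependency set, the
package carries a minimal reader/writer (348-byte header, common integer
and float datatypes, both endiannesses). Spacing comes from the sform
affine's column norms when present, else `pixdim`; orientation is ignored
deliberately — every computed quantity is intrinsic (areas, volumes,
component counts), not positional.

## Synthetic shapes: the stated world for geometry

`generate_shape()` digitizes analytic solids (voxel centre inside the
solid ⇔ foreground) with automatic grid sizing (even counts per axis,
half-integer centre, ≥3 voxel background margin, so meshes are closed and
cubes digitize to exact voxel counts). Balls, cubes, ellipsoids and
truncated balls carry closed-form volume/area references (Knud Thomsen
approximation, $p = 1.6075$, for ellipsoid area; spherical-cap formulas
for truncated balls). Bumpy balls perturb the radius with
$r(\hat{x}) = R\,(1 + a f(\hat{x}))$, where $f$ is a seeded sum of rotated
zonal harmonics $\sum_j c_j P_{\ell_j}(u_j \cdot \hat{x})$ with degrees
$\ell_j$ capped at `bump_degree`, normalized to $\sup|f| = 1$. The basis
is smooth and degree-limited by construction, so shapes stay star-shaped
and unifocal over the documented parameter range — voxel noise would not
guarantee either. Generation is fully deterministic in the spec (seed
included); the acceptance suite checks mask-byte determinism and that
measured SI increases monotonically with bump amplitude.

## Synthetic cohorts: the stated world for statistics

Covariates are drawn to match the marginal structure of a two-centre
resected-glioblastoma cohort: volume log-normal (median 30.7 mL, log-IQR
matched to quartiles 10.1–56.0), SI as $1 + $ log-normal (median 1.26,
quartiles ≈ 1.16–1.49), dural contact in 87% of cases with the covered
fraction log-normal (median 7.5%) and a point mass at zero otherwise, age
normal (65 ± 10, truncated 18–90), sex 163/271 male, MGMT methylated
122/265, EOR with a GTR point mass and median 98.4%. CSA is **not**
sampled: it is derived through the exact geometric identity
$\mathrm{CSA} = (1 - d)\cdot SI \cdot A_{sphere}(V)$ — the same definition
the morphometry uses — because only marginals are known and the identity
must hold. The postoperative-KPS distribution and the GTR rate are not
reported anywhere usable, so their defaults (mass concentrated at 70–90;
30% GTR) are declared surrogates chosen once for clinical plausibility.

Survival follows a Weibull proportional hazards model,
$S(t\,|\,x) = \exp\!\big(-(t/\lambda)^k e^{\eta}\big)$, $k = 1.2$ (rising
hazard, closed-form inverse-transform sampling), with
$\eta = \sum_j \beta_j (x_j - c_j)$ over centred covariates. Default
log-hazard ratios are the published multivariable SI-model estimates
(SI 2.223, volume 1.004/mL, MGMT 0.475, age 1.037/yr, KPS 0.934/point,
EOR 0.142 per unit fraction — the 0.142 is only dimensionally plausible
per resection *fraction*, so models code `eor_percent/100`). The baseline
scale $\lambda = 579$ days puts the null-covariate median at ≈14 months;
the resulting observed median survival lands near 13.5–13.9 months.
Censoring is administrative: uniform accrual over a 10-year window with a
single end of study, so follow-up is $U(0, \mathrm{window})$.

A config switch (`kps_decay_day = 300`) makes the KPS log-hazard drop to
zero after day 300 (piecewise inversion), generating exactly the
proportional-hazards violation that a one-off postoperative functional
score produces in real data.

**What a green test establishes — and what it does not.** The simulation
validates *recovery*: that the pipeline's estimators return the generating
values under the stated world. It does not reproduce the real cohort's
numbers (the patient data are access-restricted), does not model
covariate correlations beyond the CSA identity, and says nothing about
segmentation quality, which is upstream of this package.

## Survival-analysis conventions

* **Ties**: Efron (the default of mainstream Cox implementations);
  Breslow by flag.
* **Step function**: follow-up split at day 300 into half-open
  `(start, stop]` episodes; an event exactly at day 300 belongs to the
  first episode (counting-process convention; the boundary rule is not
  standardized, so it is fixed and documented here). `kps_early` carries
  the KPS value before the split and 0 after; `kps_late` vice versa.
  Episode splitting conserves total follow-up and event counts exactly.
* **Proportionality**: scaled Schoenfeld residuals vs KM-transformed time
  (`survival::cox.zph`), flagged at p < 0.05.
* **Model membership is fixed** to the two published sets (measure +
  volume + MGMT + age + split KPS + EOR); it is not re-selected from the
  univariable screen.
* **Missing data**: complete-case per model, with `n_used` reported.
* **No multiplicity adjustment** by default (mirroring the exploratory
  setting); Benjamini--Hochberg is available as an option.
* Months are days / 30.4375. The Cox timescale is days; hazard ratios are
  timescale-free.
* Shapiro--Wilk is limited to n ≤ 5000; longer vectors are thinned
  deterministically by index.

## Numerical and degenerate-input policy

* Mesh extraction pads the grid by two background voxels, so meshes are
  closed even for masks touching their bounding box.
* Degenerate (zero-area) faces contribute zero to TSA and trigger a
  warning with their count.
* `extent_of_resection()` rejects `post > pre` ("growth or registration
  mismatch") rather than clipping.
* Cox fits refuse constant predictors and models with fewer than two
  events by name; estimation failure (separation/collinearity) is an
  error naming the predictor, matching the brute-force oracle's behaviour
  of reporting no finite maximizer.
* Strict monotone convergence is asserted for the *area* estimator, where
  it is a property of the method; voxel-count volume error fluctuates at
  the $10^{-4}$ level once small, so tests require decay from the
  coarsest grid rather than strict ordering.

## Known limitations

* The dural-contact tolerance is a surrogate for manual dura
  segmentation; absolute dural fractions shift by $O(2\pi R \tau)$ for
  compact shapes.
* The NIfTI reader covers the common single-file layouts only (no
  `.hdr/.img` pairs, no extensions beyond skipping them).
* The cohort generator samples covariates independently (except the CSA
  identity); real covariate correlations (e.g. CSA with EOR) are not
  emulated, so univariable-screen behaviour on synthetic cohorts is
  conservative.
* No registration or segmentation: masks are taken as given, in a shared
  physical frame per case.
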
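---
title: "laminaRD: methods, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{laminaRD: methods, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(laminaRD)
```

## Overview

`laminaRD` analyzes how a diffusion-tensor metric — primarily radial
diffusivity (RD) — varies across cortical depth and cortical regions,
and converts region-by-depth differences between two reference groups
into an individualized percentile score of similarity to the cognitively
normal versus the dementia reference. This vignette documents the model
assumptions, every tunable parameter that matters, what the synthetic
generator does and does not emulate, and the numerical and design
decisions taken where more than one reasonable choice existed.

## The analysis model

**Columns.** A cortical column is the straight segment joining an
index-matched pial vertex to its white/gray-interface vertex. No
curvature or streamline bending is modeled: the surfaces are assumed to
be generated by software (e.g. FreeSurfer) that produces index-matched
meshes whose vertex pairs are approximately normal to the cortical
sheet. Columns shorter than `min_length_mm` (default 0.5 mm) are
dropped as degenerate.

**Depth sampling.** Each column is sampled at 21 equidistant fractional
depths 0%, 5%, ..., 100% (0% = pial). Depth is arc-length fraction
along the straight segment — *equidistant*, not equivolumetric,
spacing. Samples are trilinear interpolations of the metric volume;
voxel indices are 0-based and the affine maps voxel centers to mm. An
optional 4×4 matrix (e.g. an inverse boundary-based registration)
transforms column endpoints from anatomical to diffusion space before
sampling.

**Binning.** Profiles are averaged over all usable columns of a region
(unweighted), then within eight 10%-wide depth bins, 10–20% through
80–90%. Bin *k* averages the three samples at depths 10k, 10k+5, and
10(k+1)%; boundary samples are shared by adjacent bins. The analysis
this package implements fixes the 21 depths and the eight bins but
leaves the 21-point-to-8-bin mapping open; the shared-boundary scheme
was chosen
because it uses every interior sample exactly as often as its bin
coverage implies and keeps each bin an average of three samples. The
0–10% and 90–100% depths never contribute, which suppresses CSF and
white-matter partial-volume contamination at the two surfaces.

**Group screening.** For every region × bin combination, the two
reference groups are compared with one-tailed tests in both directions,
so a selection carries the sign of the difference. Welch's
unequal-variance statistic is the default (`test = "student"` gives the
pooled-variance version): nothing guarantees equal variances between a
normal-control and a dementia group. Benjamini–Hochberg correction is
applied across all combinations, by default separately within each
direction's family at q ≤ 0.025 (`fdr_family = "combined"` merges both
directions into one family; the per-direction default mirrors running
two one-tailed analyses at 0.025 each). Combinations with zero variance
in both groups and equal means are degenerate: they are assigned
p = 0.5 by convention, excluded from the FDR family (reducing its
size), and counted in the result's metadata.

**Individual percentile.** For each screened combination, a logistic
model of class membership (1 = normal reference, 0 = dementia
reference) against the metric value is fitted by penalized maximum
likelihood and the participant's value x is mapped to
100·plogis(β₀ + β₁x). "Percentile" is operationalized as 100 × the
fitted class-1 probability: the sigmoid-to-percentile mapping is a
convention of this package, and this reading matches both
the 0–100 scale and the interpretation that high values mean
similarity to the normal group. A rank-based alternative (position of
the value within the pooled reference values) is available via
`method = "rank"`. The combined percentile is the unweighted mean over
the high-confidence combinations (q ≤ 0.0025). When the participant
under test belongs to a reference group they are excluded from that
group before fitting (leave-one-out); the selection masks themselves
are *frozen* from the full-cohort screening and not recomputed under
leave-one-out — only the reference fit is defined as leave-one-out
here, and recomputing masks per participant would make
the scores of different participants incomparable. This is a
documented limitation: a reference participant contributes to the
selection of the combinations they are later scored on.

**Ridge penalty.** With reference groups of ~16 and ~11 and a strong
group difference, complete separation is likely, under which the
unpenalized maximum-likelihood slope diverges. The fit therefore adds a
ridge penalty (default `ridge = 1e-4`, applied to the slope only, on
the standardized-value scale) and solves by damped Newton iterations
with a fixed zero start, a 1e-10 step tolerance, and at most 200
iterations, making it deterministic. As ridge → 0 on non-separable data
the fit converges to the ordinary logistic regression (verified against
`glm` in the tests). The intercept is never penalized, so the fitted
probability at the pooled center is not shrunk.

## Tensor fitting

The per-voxel diffusion tensor is estimated by ordinary least squares
on the log-signal against the six tensor components plus log-S0 — the
standard log-linearized fit. Weighted or iteratively reweighted
variants would lower noise-induced bias at low SNR but are unnecessary
at the noise levels simulated here; the fitter is deliberately simple
and replaceable. Voxels with any non-positive signal are flagged and
excluded; the default mask keeps voxels whose mean b = 0 signal exceeds
an Otsu threshold. Negative eigenvalues in noisy voxels are *retained*,
not clipped, and metrics are computed from them as defined —
transparency about bad voxels was preferred over cosmetic
non-negativity. Eigenvalues are computed in closed form (trigonometric
solution for symmetric 3×3 matrices), vectorized across voxels, and
sorted descending; RD = (λ₂+λ₃)/2, AD = λ₁, MD = mean, FA is the
normalized eigenvalue dispersion with FA ≡ 0 where all eigenvalues
vanish.

## The synthetic generator

The generator emulates the statistical structure the analysis assumes,
at desk scale:

* **Design.** Four groups of 17/16/15/12 participants (normal
  amyloid-negative, normal amyloid-positive / stage-1 AD, MCI, AD
  dementia); amyloid-beta 42/40 ratios drawn uniformly on
  (0.058, 0.098] for group 1 and [0.018, 0.058) for groups 2–4, around
  the clinical cutoff 0.058; optional missingness in group 4.
* **Baseline depth profile.** RD decreasing linearly from 1.1e-3 to
  0.7e-3 mm²/s between the pial surface and the WM/GM interface. Only
  the decreasing *shape* is empirically constrained (it is the gradient
  observed in vivo and ex vivo); the endpoints are configuration
  defaults of cortical-diffusivity magnitude, not ground truth.
* **Effect structure.** Group severity (default 0, 0.04, 0.09,
  0.15 × 1e-3 mm²/s) is added to the AD-vulnerable regions — by default
  the bilateral middle temporal, fusiform, parahippocampal, and
  entorhinal cortices — scaled by per-bin depth weights that peak at
  the 30–40% bin (middle cortical layers). The severities correspond to
  a ~4–17% elevation over the cortical baseline, the magnitude range
  reported for cortical diffusivity differences along the AD continuum;
  no published effect sizes exist for this exact quantity, so these are
  free parameters chosen once, not estimates.
* **Noise.** A per-participant random intercept (SD 0.04e-3 mm²/s,
  added uniformly to all regions and depths) models between-subject
  diffusivity offsets; cell-level Gaussian noise (SD 0.02e-3 mm²/s)
  models measurement error. DWI signals get additive Gaussian noise;
  Rician noise is deliberately omitted — at the simulated SNR
  (S0/σ ≫ 3) the Gaussian approximation is standard, and the
  simplification is stated rather than hidden.
* **Planted decliners.** Optionally, `n_decliners` group-2 participants
  receive `decliner_elevation` of extra AD-region diffusivity,
  emulating asymptomatic stage-1 participants whose microstructure
  already looks dementia-like and who convert at follow-up. Defaults to
  off.
* **Geometry.** The phantom is a spherical shell "brain": two
  concentric shells with index-matched vertices on shared radii, so
  every column is exactly radial with known length, and region labels
  form contiguous angular sectors. Voxels inside/outside the ribbon get
  distinct WM/CSF constants (0.45e-3 / 2.5e-3 mm²/s) so partial-volume
  behavior at the surfaces is exercised.

Two paths produce the central participant × region × bin table: the
image-level path (fields or full DWI simulations on the phantom grid,
through the same sampling code as real data) and a table-level fast
path with the identical effect parameterization, which bypasses imaging
to test the statistical stages directly. With zero noise the two paths
agree within interpolation error (≲1.3% relative on a 0.5 mm grid when
the outside-ribbon constants are set to the baseline endpoints; with
the default partial-volume constants the boundary bins deviate by
design — that is precisely the contamination the 10–90% restriction
protects against).

What the generator does **not** emulate — and hence what passing tests
cannot show about real data: cortical folding and the resulting
column-length and orientation variability, gyral/sulcal sampling bias,
equivolumetric laminar geometry, Rician noise, motion/distortion
artifacts, atrophy-induced partial-volume differences between groups,
and any realistic spatial covariance between neighboring regions.

## Numerical choices and degenerate inputs

* Trilinear interpolation everywhere (no particular interpolant is
  mandated by the method; trilinear is smooth, fast, and admits an exact
  brute-force oracle, which the tests exploit to 1e-12).
* Sample points outside the volume flag the whole column as missing;
  regions with no usable columns are reported missing rather than
  silently dropped.
* Grid spacing is a parameter (`grid_spec$spacing_mm`) rather than a
  fixed 0.5 mm, because whether sampling should occur on an
  interpolated 0.5 mm grid or the native grid is not separable from the
  published pipeline.
* Deterministic separation in a Welch test (both variances zero,
  unequal means) yields a directional p of exactly 0 or 1 rather than
  an error; only the both-zero-variance-equal-means case takes the
  flagged p = 0.5 convention.
* For table-level cohorts, the single wide 10–90% bin is computed as
  the mean of the eight bin values (the generator defines values at bin
  granularity); the image-level path uses the true 17-sample mean.
* All randomness flows from a single root seed through fixed per-stage
  derivations, so every generator and pipeline stage is bit-reproducible.
* Voxel-based regional means rasterize each column at `step_mm`
  (default 0.25 mm) steps; a voxel touched by columns of different
  regions is assigned to the region of the closest passing sample.

## Problem sizes used by the test suite

The statistical properties are verified at the full design size (68
regions × 8 bins, 60 participants) for single analyses, and at reduced
sizes for replicated properties: 200 zero-effect and 100
effect-bearing replicates for FDR calibration/power (full 544-combination
family), 50 replicated cohorts with 12 regions for score recovery, and
a 6-region phantom with ~30k voxels per volume for the image-level
end-to-end run. These sizes were chosen so the whole suite runs in a
few minutes on one core while keeping every family and sample size that
matters to the statistics at its design value.

## Known limitations

* Straight-segment columns and equidistant depth are approximations;
  equivolumetric coordinates would shift bin contents in highly curved
  cortex (not represented in the phantom).
* Frozen selection masks mean reference participants influence the
  combinations they are scored on (see above).
* The log-linear tensor fit is unweighted; at genuinely low SNR a
  weighted fit would be preferable.
* Covariates (age, sex), permutation inference, and spatial cluster
  correction are out of scope.
* The percentile is a within-cohort similarity score, not a calibrated
  probability of decline; no external validation is modeled.
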
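---
title: "MRI-less Centiloid quantification: models, parameters, and validation"
author: "centiloidr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{MRI-less Centiloid quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(centiloidr)
```

## The problem

Amyloid PET quantification on the Centiloid scale conventionally requires a
structural MRI: the PET image is co-registered to the subject's T1 image,
the T1 is warped to template space, and that warp carries the PET along, so
that standard cortical and whole-cerebellum VOIs can be applied. When no
MRI is available, the PET image must be normalized using its own, much
poorer, anatomical contrast. `centiloidr` implements that MRI-less route:
PET-to-PET registration onto an *adaptive template*, followed by SUVr
measurement and the Centiloid calibration algebra for PiB and four
^18^F-labeled tracers (florbetapir/FBP, flutemetamol/FMM, florbetaben/FBB,
NAV4694/NAV).

The difficulty the adaptive template addresses is that amyloid-negative and
amyloid-positive scans look categorically different: negatives show
white-matter-dominant uptake, positives show cortical uptake. Registering
every subject to a single average template biases the normalization for one
of the two classes. The adaptive template is a per-subject voxelwise
mixture

$$A(w) = w \cdot A_{neg} + (1 - w) \cdot A_{pos}, \qquad w \in [0, 1],$$

where $A_{neg}$ and $A_{pos}$ are averages of spatially normalized
amyloid-negative and amyloid-positive PET scans, and $w$ is tuned per
subject by maximizing the normalized mutual information (NMI) between the
affinely registered image and $A(w)$.

## The pipeline

`normalize_pet()` runs three stages:

1. **Affine (12-dof)** registration of the subject PET to the *mixed*
   template $A(0.5)$, by Powell direction-set search maximizing NMI over a
   3-level multiresolution pyramid (downsampling factors 4, 2, 1).
2. **Weight optimization** on the affinely resampled image: Powell's method
   in one dimension degenerates to a single line search, so $w$ is found by
   a bounded Brent (parabolic/golden-section) search over $[0, 1]$,
   initialized at $w = 0.5$, tolerance $10^{-3}$. The weight is optimized
   once, between the affine and nonlinear stages, and is never allowed to
   report a lower NMI than the $w = 0.5$ starting point.
3. **Nonlinear registration** to $A(w^\*)$ by a cubic B-spline free-form
   deformation (FFD) with 20-mm control-point spacing, maximizing NMI minus
   a bending-energy penalty by gradient ascent with an analytic similarity
   gradient.

SUVr is then the weighted mean of the normalized image over the cortical
target VOI divided by the weighted mean over the whole-cerebellum reference
VOI; mask values act as weights, so binary masks reduce to plain means.

## Calibration algebra

The Centiloid scale is anchored by the mean PiB SUVr of a young-control
cohort (YC-0, $1.014$) and a typical-AD cohort (AD-100, $2.088$):

$$CL = 100 \cdot \frac{S - S_{YC0}}{S_{AD100} - S_{YC0}}.$$

A tracer or pipeline other than standard-pipeline PiB is first mapped to a
PiB-equivalent SUVr by inverting its calibration line $S_{tracer} = m
\cdot S_{PiB} + b$, fitted with PiB as the independent variable
(`fit_calibration()`). Composing the two steps gives the closed form
`compose_equation()`: $CL(s) = 100 (s - \text{offset}) / \text{divisor}$
with $\text{offset} = b + m S_{YC0}$ and $\text{divisor} = m (S_{AD100} -
S_{YC0})$.

`coefficient_registry()` bundles the published 3-decimal coefficients for
all ten tracer-pipeline combinations. Composing them reproduces the
published conversion-equation constants at 3 decimals wherever the printed
inputs permit; a handful of published constants were evidently computed
from unrounded internal values (for example the PiB non-standard divisor
prints 0.993 where 3-dp inputs compose to 0.992), and the tests assert
those at ±0.001 rather than forcing agreement. PiB under the standard
pipeline is represented as the identity calibration ($m = 1$, $b = 0$), so
the anchor equation and the composed equation coincide.

Level-1 replication quality control (`level1_qc()`) applies the published
acceptance ranges: slope in $[0.98, 1.02]$ (inclusive), intercept in
$[-2, 2]$ (inclusive), $R^2 > 0.98$ (strict).

## Registration internals and numerical choices

**NMI definition.** The reported similarity (`nmi()`) is the Studholme
normalization $(H(F) + H(M)) / H(F, M)$ from a hard-binned 64-bin joint
histogram over all finite voxels, background included. It lies in
$[1, 2]$; self-similarity is exactly 2.

**Optimization metric.** Hard binning makes the metric surface noisy, and
with voxel-aligned noise it develops spurious extrema at integer-voxel
shifts (interpolating at fractional offsets smooths noise and inflates the
apparent similarity). The optimizers therefore work on a linear-binned
(first-order Parzen) variant of the same quantity with frozen intensity
ranges, and both images receive a mild 1-voxel-sigma Gaussian smoothing at
the finest pyramid level. The hard-binned NMI remains the reported,
normative value: every registration records `nmi_init` and `nmi_final`, and
a result that fails to improve the normative metric is replaced by its
initialization and flagged rather than returned silently.

**Tie handling.** The hard-binned NMI is singular at bit-exact alignment
(any interpolation at all costs a little of it), so an optimum within
measurement precision of the initialization (0.05 mm / 0.05 deg) snaps to
the initialization exactly; only a material drop (> 0.01 NMI) counts as an
optimization failure.

**Powell search.** Rigid (6-dof) and affine (12-dof) parameters —
translations (mm), rotations (deg), log-scales, shears, all about the
fixed image's centre of mass — are optimized by cyclic Brent line searches
with Powell's extrapolation direction appended each cycle; 8/5/4 cycles at
the three pyramid levels; at most 30 000 metric samples per level (finer
levels are strided). Everything is deterministic: there is no RNG anywhere
in the registration path.

**FFD.** The control lattice covers the fixed grid plus a one-point cubic
B-spline margin. The similarity gradient is analytic: the derivative of
the linear-binned joint histogram with respect to each warped sample's
intensity is chained through the trilinearly sampled image gradient and
scattered back to the control points with the B-spline tensor weights. The
penalty is the mean squared second difference of the control lattice along
each axis (weight 0.001 relative to the similarity; cross-terms omitted),
and its gradient is the corresponding discrete biharmonic. Ascent uses a
backtracking step on the objective, starting at 2 mm and stopping below
0.05 mm or when the objective improves by less than $10^{-7}$; two pyramid
levels (2, 1) with at most 45/20 iterations.

**Resampling.** All transforms are applied by pull-back: target voxel
centres are mapped through the transform into the moving volume and
interpolated there (trilinear for intensities, nearest-neighbour for
binary masks, which therefore stay binary). Out-of-support voxels are
zero-filled and excluded from downstream VOI means via a validity mask.

## The phantom generator

The synthetic data module emulates the statistical structure the pipeline
assumes, with fully known ground truth. The anatomy is defined in world
millimetres (hence resolution-invariant): an ellipsoidal head with a
skull/scalp shell, a cerebral ellipsoid split into a white-matter core and
a cortical ribbon (~36% of brain volume), a separate cerebellar blob used
as the SUVr reference, and soft-tissue filler. Intensities are relative to
cerebellum = 1, so the cortical level *is* the true SUVr: burden 0 renders
the YC-0 anchor level 1.014, burden 1 the AD-100 level 2.088, linearly in
between. Nonspecific white-matter binding distinguishes tracer classes
(1.6 for FBP/FMM/FBB, 1.1 for PiB/NAV); these are configuration values
motivated by the qualitatively lower white-matter binding of PiB and NAV,
not calibrated claims. The optional skull shell intensity can be raised to
emulate FBB-like diploe uptake, a known failure mode of PET-only
normalization.

Rendering order is: classify each voxel centre *through* the ground-truth
warp (analytically, so no interpolation error enters the truth), apply a
Gaussian PSF (default 8 mm FWHM, a typical reconstructed PET resolution),
then add seeded voxelwise Gaussian noise (default SD 5% of cerebellar
intensity). Ground-truth warps are either explicit affines or smooth
random B-spline fields scaled so their maximum displacement equals the
requested amplitude. All randomness is seed-isolated: generation is
bit-reproducible and never disturbs the caller's RNG stream.

Cohorts (`make_cohort()`) draw true PiB SUVr from the anchor
distributions, Normal(1.014, 0.047) for negatives and Normal(2.088, 0.209)
for positives, and link a tracer SUVr through the standard calibration
line plus Normal(0, 0.06) residual. The cortical level renders the sampled
SUVr directly rather than a value clamped into the burden range: clamping
would truncate the negative cohort's distribution at its own mean and bias
the sample mean upward by about half a standard deviation, destroying the
anchor statistics the generator exists to emulate. The recorded `burden`
field is the clamped equivalent.

The phantom's VOI masks are the cortical ribbon and cerebellar compartments
eroded by one voxel, which keeps partial-volume contamination of the
measured means small without hiding it: at the default 8-mm PSF a
mid-burden phantom still reads ~5% low, in the partial-volume direction,
and the test-suite asserts that bias stays below 10%. The template-averaging
test uses a 4-mm PSF so that it isolates averaging fidelity instead of
re-measuring that dilution.

## What the phantoms do and do not show

Passing phantom tests demonstrate that the pipeline recovers known
transforms (translations/rotations to ~0.1 mm/0.1 deg, scales to ~0.005,
smooth 4-mm warps to ≤1.5 mm mean residual), recovers mixture weights to
±0.03, and propagates SUVr through the full normalization with <3% error
under the stated noise and blur. They do not show robustness to real
anatomical variability (ventricle size, atrophy, cerebellar CSF spaces),
scanner harmonization differences, motion, or reconstruction artifacts;
the phantom head is a single geometry, not a population. Tracer kinetics
are reduced to two white-matter classes. Conclusions about real cohorts
require real calibration data; the package's contribution is the
machinery, validated where ground truth can be known exactly.

## Problem sizes and defaults

The template grid defaults to 160×160×96 voxels at 1.5 mm
(`default_template_grid()`). The whole validation suite runs on a
64×64×48 / 3-mm grid (`test_grid()`) — the same field of view at coarser
sampling — with template pairs averaged from 6 + 6 rendered phantoms and
cohort statistics taken at the published group sizes (34/45/74) without
rendering volumes where only SUVr values are needed. These sizes are the
package's validation design; all tolerances above refer to them.

## Known limitations

* One template pair serves all tracers; tracer-specific templates would
  likely register ^18^F tracers better but need tracer-specific data.
* The FFD is not guaranteed diffeomorphic; large steps are prevented only
  by the bending penalty and the backtracking line search.
* `optimize_weight()` evaluates NMI on the full volume (no head mask);
  with heavy background clutter a masked variant would be preferable.
* The weight is optimized once, before the FFD, never re-optimized after.
* Relative variance is implemented as an SD ratio because that is what
  reproduces every published table value; the name is kept for
  compatibility with the field's usage.
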
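# centiloidr

Centiloid quantification of amyloid PET **without structural MRI**, in R.

Amyloid PET tracers (PiB and the ^18^F-labeled tracers florbetapir/FBP,
flutemetamol/FMM, florbetaben/FBB, NAV4694/NAV) are compared across sites
and tracers on the **Centiloid scale**, a linear rescaling of the PiB SUVr
(cortical-to-whole-cerebellum uptake ratio) anchored at 0 for young
controls and 100 for typical AD:

    CL = 100 * (SUVr - 1.014) / (2.088 - 1.014)

Computing the SUVr requires warping each PET image into template space,
which conventionally leans on the subject's structural MRI. `centiloidr`
implements the MRI-less alternative: registration of the PET image itself
to an **adaptive template** `A(w) = w * Aneg + (1 - w) * Apos`, a
per-subject mixture of amyloid-negative and amyloid-positive PET
templates whose weight `w` is tuned by maximizing normalized mutual
information (NMI). The pipeline is: affine registration to the mixed
template `A(0.5)` → one-dimensional Powell (Brent) optimization of `w` →
cubic B-spline free-form deformation (20-mm control spacing) to `A(w*)` →
VOI-based SUVr → Centiloid conversion.

The package is aimed at imaging methodologists who need a scriptable,
fully deterministic, dependency-light implementation of this workflow —
including the complete level-1/level-2 calibration algebra, the agreement
statistics used to validate pipeline substitutions (R², regression slope
bias, ICC(A,1), relative variance), and a seeded synthetic phantom module
that provides ground truth for every stage.

## What's inside

| Area | Functions |
|---|---|
| NIfTI-1 I/O, grids, resampling | `read_volume`, `write_volume`, `reorient_by_header`, `resample_to` |
| Registration | `nmi`, `register_rigid`, `register_affine`, `register_ffd`, `apply_transform`, `save_transform` |
| Adaptive template | `build_template`, `mix_template`, `optimize_weight`, `normalize_pet` |
| Quantification | `compute_suvr`, `centiloid_from_pib`, `pib_equivalent_suvr`, `compose_equation`, `fit_calibration`, `level1_qc`, `coefficient_registry`, `centiloid_batch` |
| Agreement statistics | `regression_agreement`, `icc_absolute_single`, `relative_variance`, `pipeline_agreement` |
| Synthetic phantoms | `make_anatomy`, `render_pet`, `make_cohort`, `make_voi_set` |
| CLI | `cli_main` + `inst/cli/centiloid.R` (subcommands `simulate`, `build-template`, `normalize`, `suvr`, `centiloid`, `calibrate`, `validate`) |

## Worked example

```r
library(centiloidr)

# amyloid-negative / amyloid-positive templates from seeded phantom cohorts
neg <- make_cohort(6, 0, seed = 101)
pos <- make_cohort(0, 6, seed = 102)
pair <- template_pair(
  build_template(lapply(neg, `[[`, "volume"), "negative"),
  build_template(lapply(pos, `[[`, "volume"), "positive"))

# a mid-burden subject, off-grid by a known rotation + translation
A <- diag(4); d <- pi / 180 * 3
A[1:2, 1:2] <- rbind(c(cos(d), -sin(d)), c(sin(d), cos(d)))
A[1:3, 4] <- c(4, -3, 2)
sub <- render_pet(phantom_spec(burden = 0.3, seed = 21,
                               deformation = list(type = "affine", matrix = A)))

res <- normalize_pet(sub$volume, pair)
res
#> <normalization_result> w = 0.603, final NMI 1.31774, mean |u| 0.20 mm

s <- compute_suvr(res$normalized, make_voi_set())
s
#> <suvr_result> SUVr 1.3149 (target 1.1843 / reference 0.9007)

centiloid_from_pib(s$suvr)
#> [1] 28.0174
```

The adaptive weight `w = 0.60` sits on the amyloid-negative side, as it
should for burden 0.3; the measured SUVr 1.31 is within 3% of the same
phantom measured without any deformation (1.28; the residual reflects
registration error only, since blur and noise are identical), and the
Centiloid value follows by the anchor formula.

Converting a batch of SUVr values with the bundled published coefficients:

```r
centiloid_batch(data.frame(subject_id = "s1", tracer = "FBP",
                           pipeline = "nonstandard", suvr = 1.3))
#>   subject_id tracer    pipeline suvr pib_equivalent_suvr centiloid
#> 1         s1    FBP nonstandard  1.3            1.426407  38.39916
```

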
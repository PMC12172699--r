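Package: centiloidr
Title: MRI-Less Centiloid Quantification for Amyloid PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies amyloid burden on the Centiloid scale from brain PET
    without structural MRI. Implements adaptive-template spatial
    normalization (a per-subject mixture of amyloid-negative and
    amyloid-positive PET templates, weighted by maximizing normalized mutual
    information), rigid/affine and cubic B-spline free-form-deformation
    registration, VOI-based SUVr computation, the full Centiloid level-1 and
    level-2 calibration algebra for PiB and four 18F-labeled tracers with a
    bundled coefficient registry, agreement statistics (R-squared, slope
    bias, ICC(A,1), relative variance), and a deterministic synthetic
    phantom generator with known ground truth for end-to-end validation.
License: MIT
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
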
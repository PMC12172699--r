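#' Target / reference VOI pair
#'
#' Couples the cortical target mask and the whole-cerebellum reference mask
#' used for SUVr. Both masks must share a grid, be nonempty, and overlap by
#' at most 1% of the target weight.
#'
#' @param target,reference [mask_volume]s.
#' @param space_label free-text space tag (e.g. "MNI-152 2 mm").
#' @export
voi_set <- function(target, reference, space_label = "") {
  stopifnot(inherits(target, "mask_volume"), inherits(reference, "mask_volume"))
  if (!identical(dim(target$data), dim(reference$data)) ||
      max(abs(target$affine - reference$affine)) > 1e-6)
    stop("voi_set: masks must share one grid")
  ov <- sum(pmin(target$data, reference$data))
  if (ov > 0.01 * sum(target$data))
    stop("voi_set: target/reference overlap exceeds 1% of target weight")
  structure(list(target = target, reference = reference,
                 space_label = space_label), class = "voi_set")
}

#' SUVr from VOI-weighted means
#'
#' Weighted mean uptake in the cortical target mask divided by the weighted
#' mean in the whole-cerebellum reference mask. Mask values act as weights,
#' so binary masks reduce to plain means. Voxels flagged invalid by an
#' earlier resampling (out-of-support) are excluded.
#'
#' @param vol a `pet_volume`; resampled onto the VOI grid if needed.
#' @param vois a [voi_set].
#' @return An `suvr_result`: `suvr`, `target_mean`, `reference_mean`,
#'   `n_target_voxels`, `n_reference_voxels`.
#' @export
compute_suvr <- function(vol, vois) {
  stopifnot(inherits(vol, "pet_volume"), inherits(vois, "voi_set"))
  g <- as_grid(vois$target)
  if (!identical(dim(vol$data), g$dim) ||
      max(abs(vol$affine - g$affine)) > 1e-6)
    vol <- resample_to(vol, g, "trilinear")
  valid <- vol$meta$validity
  wmean <- function(mask) {
    w <- mask$data
    if (!is.null(valid)) w <- w * valid
    n_bad <- sum(w > 0 & !is.finite(vol$data))
    if (n_bad > 0)
      stop("compute_suvr: ", n_bad, " non-finite voxels inside mask")
    list(mean = sum(w * vol$data) / sum(w), n = sum(w > 0))
  }
  tg <- wmean(vois$target)
  rf <- wmean(vois$reference)
  if (!is.finite(rf$mean) || rf$mean <= 0)
    stop("compute_suvr: reference mean is not positive (",
         format(rf$mean), ")")
  structure(list(suvr = tg$mean / rf$mean, target_mean = tg$mean,
                 reference_mean = rf$mean, n_target_voxels = tg$n,
                 n_reference_voxels = rf$n), class = "suvr_result")
}

#' @export
print.suvr_result <- function(x, ...) {
  cat(sprintf("<suvr_result> SUVr %.4f (target %.4f / reference %.4f)\n",
              x$suvr, x$target_mean, x$reference_mean))
  invisible(x)
}

#' Centiloid anchor points
#'
#' The level-1 anchors of the Centiloid scale: the mean PiB SUVr of the
#' young-control (YC-0, Centiloid 0) and typical-AD (AD-100, Centiloid 100)
#' calibration cohorts. Defaults are the bundled replication values
#' 1.014 and 2.088.
#'
#' @param yc0_mean,ad100_mean anchor PiB SUVr means; requires
#'   `ad100_mean > yc0_mean > 0`.
#' @export
centiloid_anchors <- function(yc0_mean = 1.014, ad100_mean = 2.088) {
  if (!(ad100_mean > yc0_mean && yc0_mean > 0))
    stop("centiloid_anchors: need ad100_mean > yc0_mean > 0")
  structure(list(yc0_mean = yc0_mean, ad100_mean = ad100_mean),
            class = "centiloid_anchors")
}

#' PiB SUVr to Centiloid
#'
#' `CL = 100 * (suvr - yc0) / (ad100 - yc0)`: the linear rescaling that
#' sends the young-control anchor to 0 and the AD anchor to 100.
#'
#' @param suvr PiB SUVr value(s).
#' @param anchors a [centiloid_anchors].
#' @export
centiloid_from_pib <- function(suvr, anchors = centiloid_anchors()) {
  stopifnot(inherits(anchors, "centiloid_anchors"))
  100 * (suvr - anchors$yc0_mean) / (anchors$ad100_mean - anchors$yc0_mean)
}

#' Tracer calibration line
#'
#' Slope/intercept of the regression of a tracer's SUVr on standard-pipeline
#' PiB SUVr, for one pipeline flavour. Inverting it converts a tracer SUVr
#' into a PiB-equivalent SUVr.
#'
#' @param tracer `"PiB"`, `"FBP"`, `"FMM"`, `"FBB"` or `"NAV"`.
#' @param pipeline `"standard"` or `"nonstandard"`.
#' @param slope,intercept regression coefficients (slope > 0).
#' @param r2 coefficient of determination (informational).
#' @param n number of calibration pairs (informational).
#' @export
tracer_calibration <- function(tracer, pipeline, slope, intercept,
                               r2 = NA_real_, n = NA_integer_) {
  tracer <- match.arg(tracer, c("PiB", "FBP", "FMM", "FBB", "NAV"))
  pipeline <- match.arg(pipeline, c("standard", "nonstandard"))
  if (!is.finite(slope) || slope <= 0)
    stop("tracer_calibration: slope must be positive")
  structure(list(tracer = tracer, pipeline = pipeline, slope = slope,
                 intercept = intercept, r2 = r2, n = n),
            class = "tracer_calibration")
}

#' Tracer SUVr to PiB-equivalent SUVr
#'
#' Inverts the calibration line: `(tracer_suvr - intercept) / slope`.
#'
#' @param tracer_suvr tracer SUVr value(s).
#' @param calib a [tracer_calibration].
#' @export
pib_equivalent_suvr <- function(tracer_suvr, calib) {
  stopifnot(inherits(calib, "tracer_calibration"))
  (tracer_suvr - calib$intercept) / calib$slope
}

#' Tracer SUVr to Centiloid
#'
#' Composition of the PiB-equivalent conversion with the anchor rescaling.
#'
#' @inheritParams pib_equivalent_suvr
#' @param anchors a [centiloid_anchors].
#' @export
centiloid_from_tracer <- function(tracer_suvr, calib,
                                  anchors = centiloid_anchors()) {
  centiloid_from_pib(pib_equivalent_suvr(tracer_suvr, calib), anchors)
}

#' Closed-form Centiloid conversion equation
#'
#' Symbolic composition of the PiB-equivalent inversion with the anchor
#' rescaling: `CL(s) = 100 * (s - offset) / divisor` with
#' `offset = intercept + slope * yc0` and
#' `divisor = slope * (ad100 - yc0)`. Identical pointwise to
#' [centiloid_from_tracer].
#'
#' @param calib a [tracer_calibration].
#' @param anchors a [centiloid_anchors].
#' @return A `centiloid_equation` with fields `offset`, `divisor`,
#'   `tracer`, `pipeline`.
#' @export
compose_equation <- function(calib, anchors = centiloid_anchors()) {
  stopifnot(inherits(calib, "tracer_calibration"),
            inherits(anchors, "centiloid_anchors"))
  structure(list(
    offset = calib$intercept + calib$slope * anchors$yc0_mean,
    divisor = calib$slope * (anchors$ad100_mean - anchors$yc0_mean),
    tracer = calib$tracer, pipeline = calib$pipeline),
    class = "centiloid_equation")
}

#' @export
print.centiloid_equation <- function(x, ...) {
  cat(sprintf("<centiloid_equation> %s/%s: CL = 100 * (SUVr - %.3f) / %.3f\n",
              x$tracer, x$pipeline, x$offset, x$divisor))
  invisible(x)
}

#' Evaluate a composed Centiloid equation
#' @param eq a `centiloid_equation`.
#' @param suvr tracer SUVr value(s).
#' @export
centiloid_from_equation <- function(eq, suvr) {
  stopifnot(inherits(eq, "centiloid_equation"))
  100 * (suvr - eq$offset) / eq$divisor
}

#' Fit a tracer-vs-PiB calibration line
#'
#' Ordinary least squares of the tracer SUVr on the standard-pipeline PiB
#' SUVr (PiB as the independent variable).
#'
#' @param pib_suvrs,tracer_suvrs paired SUVr vectors (n >= 3).
#' @param tracer,pipeline labels for the resulting calibration.
#' @return A [tracer_calibration] with fitted `slope`, `intercept`, `r2`.
#' @export
fit_calibration <- function(pib_suvrs, tracer_suvrs, tracer = "PiB",
                            pipeline = "nonstandard") {
  if (length(pib_suvrs) != length(tracer_suvrs))
    stop("fit_calibration: inputs must be paired")
  if (length(pib_suvrs) < 3)
    stop("fit_calibration: need at least 3 pairs, got ", length(pib_suvrs))
  if (stats::var(pib_suvrs) <= 0)
    stop("fit_calibration: PiB SUVr variance is zero")
  fit <- stats::lm(tracer_suvrs ~ pib_suvrs)
  tracer_calibration(tracer, pipeline,
                     slope = unname(stats::coef(fit)[2]),
                     intercept = unname(stats::coef(fit)[1]),
                     r2 = suppressWarnings(summary(fit)$r.squared),
                     n = length(pib_suvrs))
}

#' Level-1 replication quality control
#'
#' Pass ranges for the regression of locally computed Centiloid values on
#' the published ones: slope in `[0.98, 1.02]`, intercept in `[-2, 2]`,
#' and R-squared strictly greater than 0.98.
#'
#' @param slope,intercept,r2 regression summary of the replication.
#' @return list with per-criterion booleans and overall `pass`.
#' @export
level1_qc <- function(slope, intercept, r2) {
  stopifnot(is.finite(slope), is.finite(intercept), is.finite(r2))
  slope_ok <- slope >= 0.98 && slope <= 1.02
  intercept_ok <- intercept >= -2 && intercept <= 2
  r2_ok <- r2 > 0.98
  list(slope_ok = slope_ok, intercept_ok = intercept_ok, r2_ok = r2_ok,
       pass = slope_ok && intercept_ok && r2_ok)
}

#' Bundled calibration coefficient registry
#'
#' The package's built-in constants: the level-1 anchors (1.014 / 2.088)
#' and the tracer-vs-PiB calibration lines for both pipeline flavours.
#' PiB under the standard pipeline is the identity calibration (it defines
#' the scale); all other coefficients are the published 3-decimal values.
#'
#' @return list with `anchors` (a [centiloid_anchors]) and `calibrations`
#'   (named list of [tracer_calibration]s, keys `"<tracer>.<pipeline>"`).
#' @export
coefficient_registry <- function() {
  cal <- list(
    tracer_calibration("PiB", "standard",    1.000,  0.000, NA_real_),
    tracer_calibration("PiB", "nonstandard", 0.924,  0.097, 0.993),
    tracer_calibration("FBP", "standard",    0.523,  0.511, 0.905),
    tracer_calibration("FBP", "nonstandard", 0.462,  0.641, 0.879),
    tracer_calibration("FMM", "standard",    0.770,  0.218, 0.963),
    tracer_calibration("FMM", "nonstandard", 0.703,  0.347, 0.965),
    tracer_calibration("FBB", "standard",    0.608,  0.390, 0.954),
    tracer_calibration("FBB", "nonstandard", 0.557,  0.490, 0.957),
    tracer_calibration("NAV", "standard",    1.046, -0.035, 0.991),
    tracer_calibration("NAV", "nonstandard", 0.899,  0.145, 0.990))
  names(cal) <- vapply(cal, function(x) paste(x$tracer, x$pipeline,
                                              sep = "."), "")
  list(anchors = centiloid_anchors(), calibrations = cal)
}

#' @rdname coefficient_registry
#' @param tracer,pipeline registry key.
#' @export
registry_lookup <- function(tracer, pipeline) {
  reg <- coefficient_registry()
  key <- paste(match.arg(tracer, c("PiB", "FBP", "FMM", "FBB", "NAV")),
               match.arg(pipeline, c("standard", "nonstandard")), sep = ".")
  reg$calibrations[[key]]
}

#' Registry as a data frame
#'
#' One row per tracer x pipeline with slope, intercept, R-squared, and the
#' composed Centiloid equation constants.
#' @export
registry_table <- function() {
  reg <- coefficient_registry()
  rows <- lapply(reg$calibrations, function(cal) {
    eq <- compose_equation(cal, reg$anchors)
    data.frame(tracer = cal$tracer, pipeline = cal$pipeline,
               slope = cal$slope, intercept = cal$intercept, r2 = cal$r2,
               cl_offset = eq$offset, cl_divisor = eq$divisor)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Batch SUVr to Centiloid conversion
#'
#' Adds `pib_equivalent_suvr` and `centiloid` columns to a table with
#' columns `subject_id`, `tracer`, `pipeline`, `suvr`, using the bundled
#' registry.
#'
#' @param df data frame with the required columns.
#' @return The augmented data frame.
#' @export
centiloid_batch <- function(df) {
  need <- c("subject_id", "tracer", "pipeline", "suvr")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("centiloid_batch: missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(df)
  df$pib_equivalent_suvr <- numeric(n)
  df$centiloid <- numeric(n)
  anchors <- centiloid_anchors()
  for (i in seq_len(n)) {
    cal <- registry_lookup(df$tracer[i], df$pipeline[i])
    pe <- pib_equivalent_suvr(df$suvr[i], cal)
    df$pib_equivalent_suvr[i] <- pe
    df$centiloid[i] <- centiloid_from_pib(pe, anchors)
  }
  df
}
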
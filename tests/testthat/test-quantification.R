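test_that("compute_suvr: compartment means, scale invariance, phantom truth", {
  g <- grid_spec(c(12, 12, 12), diag(4))
  tgt <- array(0, g$dim); tgt[2:5, 2:5, 2:5] <- 1
  ref <- array(0, g$dim); ref[8:11, 8:11, 8:11] <- 1
  vois <- voi_set(mask_volume(tgt, g$affine, "binary"),
                  mask_volume(ref, g$affine, "binary"))
  vol <- pet_volume(array(1, g$dim), g$affine)
  vol$data[tgt == 1] <- 1.5
  r <- compute_suvr(vol, vois)
  expect_equal(r$suvr, 1.5)
  expect_equal(r$n_target_voxels, 64L)
  expect_equal(r$suvr * r$reference_mean, r$target_mean, tolerance = 1e-12)

  scaled <- pet_volume(vol$data * 3.7, g$affine)
  expect_equal(compute_suvr(scaled, vois)$suvr, r$suvr, tolerance = 1e-12)

  ph <- render_pet(phantom_spec(burden = 1, psf_fwhm = 0, noise_sd = 0))
  expect_lt(abs(compute_suvr(ph$volume, ph$truth$masks)$suvr - 2.088) /
              2.088, 0.005)

  zero <- pet_volume(array(0, g$dim), g$affine)
  expect_error(compute_suvr(zero, vois), "not positive")
  bad <- vol; bad$data[3, 3, 3] <- NaN
  expect_error(compute_suvr(bad, vois), "1 non-finite")
})

test_that("voi_set rejects overlapping target and reference", {
  g <- grid_spec(c(8, 8, 8), diag(4))
  a <- array(0, g$dim); a[2:5, 2:5, 2:5] <- 1
  expect_error(voi_set(mask_volume(a, g$affine, "binary"),
                       mask_volume(a, g$affine, "binary")), "overlap")
})

test_that("the anchor rescaling sends 1.014 to 0 and 2.088 to 100", {
  expect_equal(centiloid_from_pib(1.014), 0)
  expect_equal(centiloid_from_pib(2.088), 100)
  expect_equal(centiloid_from_pib(1.551), 50)  # midpoint linearity
  expect_error(centiloid_anchors(2, 1), "yc0")
})

test_that("PiB-equivalent conversion inverts the calibration line", {
  cal <- tracer_calibration("FMM", "standard", 0.77, 0.218)
  expect_equal(pib_equivalent_suvr(cal$intercept + cal$slope * 1.0, cal), 1)

  fbp <- registry_lookup("FBP", "standard")
  expect_equal(pib_equivalent_suvr(1.0413, fbp), 1.014, tolerance = 1e-3)

  nav <- registry_lookup("NAV", "standard")
  expect_equal(pib_equivalent_suvr(1.046 * 2.088 - 0.035, nav), 2.088,
               tolerance = 1e-12)
})

test_that("compose_equation matches the two-step conversion pointwise", {
  reg <- coefficient_registry()
  set.seed(42)
  s <- runif(1000, 0.8, 3)
  for (cal in reg$calibrations) {
    eq <- compose_equation(cal, reg$anchors)
    expect_lt(max(abs(centiloid_from_equation(eq, s) -
                      centiloid_from_tracer(s, cal, reg$anchors))), 1e-9)
    # CL(offset) = 0, CL(offset + divisor) = 100 by construction
    expect_equal(centiloid_from_equation(eq, eq$offset), 0)
    expect_equal(centiloid_from_equation(eq, eq$offset + eq$divisor), 100)
  }
  idt <- compose_equation(tracer_calibration("PiB", "standard", 1, 0))
  expect_equal(idt$offset, 1.014)
  expect_equal(idt$divisor, 2.088 - 1.014)
})

test_that("fit_calibration: exact line, noisy recovery, degenerate input", {
  x <- seq(1, 2.5, length.out = 10)
  cal <- fit_calibration(x, 0.77 * x + 0.218, "FMM", "standard")
  expect_equal(cal$slope, 0.77, tolerance = 1e-10)
  expect_equal(cal$intercept, 0.218, tolerance = 1e-10)
  expect_equal(cal$r2, 1)

  expect_error(fit_calibration(c(1, 2), c(1, 2)), "at least 3")
  expect_error(fit_calibration(rep(1, 5), rnorm(5)), "variance")
})

test_that("level-1 QC enforces the published acceptance ranges", {
  expect_true(level1_qc(0.997, 0.166, 0.999)$pass)
  r <- level1_qc(1.03, 0, 0.999)
  expect_false(r$pass); expect_false(r$slope_ok); expect_true(r$r2_ok)
  expect_true(level1_qc(1.02, 0, 0.999)$pass)     # slope bound inclusive
  expect_false(level1_qc(1.0, 0, 0.98)$pass)      # R2 bound exclusive
  expect_false(level1_qc(1.0, 2.5, 0.99)$pass)
})

test_that("the registry carries the published coefficients", {
  expect_equal(registry_lookup("FMM", "standard")$slope, 0.770)
  pib <- registry_lookup("PiB", "standard")
  expect_equal(pib$slope, 1); expect_equal(pib$intercept, 0)
  ns <- registry_lookup("PiB", "nonstandard")
  expect_equal(ns$slope, 0.924); expect_equal(ns$intercept, 0.097)
  tab <- registry_table()
  expect_identical(nrow(tab), 10L)
  expect_true(all(tab$slope > 0))
})

test_that("centiloid_batch augments tables and handles empty input", {
  df <- data.frame(subject_id = c("a", "b"),
                   tracer = c("PiB", "FBP"),
                   pipeline = c("standard", "nonstandard"),
                   suvr = c(2.088, 1.109))
  out <- centiloid_batch(df)
  expect_equal(out$centiloid[1], 100)
  expect_lt(abs(out$centiloid[2]), 0.1)  # FBP-NS offset is 1.109
  empty <- centiloid_batch(df[0, ])
  expect_identical(nrow(empty), 0L)
  expect_true(all(c("pib_equivalent_suvr", "centiloid") %in% names(empty)))
  expect_error(centiloid_batch(df[, 1:2]), "missing columns")
})
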
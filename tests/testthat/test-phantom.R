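test_that("anatomy has all compartments, one label per voxel, sane cortex", {
  an <- make_anatomy()
  labs <- sort(unique(as.vector(an$data)))
  expect_identical(labs, as.numeric(0:5))
  # a single label array partitions the head by construction; check the
  # cerebellum is disjoint from cortex via the VOI masks
  vois <- fixture_vois()
  expect_equal(sum(vois$target$data * vois$reference$data), 0)
  brain <- sum(an$data %in% c(1, 2, 3))
  frac <- sum(an$data == 2) / brain
  expect_gt(frac, 0.2); expect_lt(frac, 0.4)
  expect_error(make_anatomy(grid_spec(c(16, 16, 16), diag(4))), "too small")
})

test_that("noise-free, blur-free phantoms hit the anchor SUVr exactly", {
  p0 <- render_pet(phantom_spec(burden = 0, psf_fwhm = 0, noise_sd = 0))
  expect_equal(compute_suvr(p0$volume, p0$truth$masks)$suvr, 1.014)
  p1 <- render_pet(phantom_spec(burden = 1, psf_fwhm = 0, noise_sd = 0))
  expect_equal(compute_suvr(p1$volume, p1$truth$masks)$suvr, 2.088)
  expect_equal(p1$truth$true_suvr, 2.088)
})

test_that("the PSF dilutes the measured SUVr toward 1, but by <= 10%", {
  ph <- render_pet(phantom_spec(burden = 0.5, psf_fwhm = 8, noise_sd = 0))
  s <- compute_suvr(ph$volume, ph$truth$masks)$suvr
  truth <- ph$truth$true_suvr
  expect_lt(s, truth)              # partial-volume direction: toward 1
  expect_gt(s, 1)
  expect_lt(abs(s - truth) / truth, 0.10)
})

test_that("rendering is deterministic in the seed", {
  a <- render_pet(phantom_spec(burden = 0.4, seed = 123))
  b <- render_pet(phantom_spec(burden = 0.4, seed = 123))
  expect_identical(a$volume$data, b$volume$data)
  c_ <- render_pet(phantom_spec(burden = 0.4, seed = 124))
  expect_false(identical(a$volume$data, c_$volume$data))
})

test_that("render_pet does not disturb the caller's RNG stream", {
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(render_pet(phantom_spec(seed = 5)))
  after <- rnorm(3)
  expect_identical(before, after)
})

test_that("cohort anchor statistics converge at 3-SE tolerance", {
  neg <- make_cohort(34, 0, seed = 1, render = FALSE)
  m_neg <- mean(vapply(neg, function(x) x$truth$pib_suvr, 0))
  expect_lt(abs(m_neg - 1.014), 3 * 0.047 / sqrt(34))

  pos <- make_cohort(0, 45, seed = 1, render = FALSE)
  m_pos <- mean(vapply(pos, function(x) x$truth$pib_suvr, 0))
  expect_lt(abs(m_pos - 2.088), 3 * 0.209 / sqrt(45))

  again <- make_cohort(34, 0, seed = 1, render = FALSE)
  expect_identical(vapply(neg, function(x) x$truth$pib_suvr, 0),
                   vapply(again, function(x) x$truth$pib_suvr, 0))
})

test_that("cohort volumes are reproducible bit-exactly by seed", {
  a <- make_cohort(1, 1, seed = 8)
  b <- make_cohort(1, 1, seed = 8)
  expect_identical(a[[1]]$volume$data, b[[1]]$volume$data)
  expect_identical(a[[2]]$volume$data, b[[2]]$volume$data)
})

test_that("tracer SUVr follows the calibration link", {
  co <- make_cohort(40, 40, tracer = "FMM", seed = 21, render = FALSE)
  pib <- vapply(co, function(x) x$truth$pib_suvr, 0)
  fmm <- vapply(co, function(x) x$truth$tracer_suvr, 0)
  fit <- stats::lm(fmm ~ pib)
  expect_lt(abs(unname(coef(fit)[2]) - 0.770), 0.05)
})

test_that("phantom VOIs are nonempty, binary, and survive identity warps", {
  vois <- fixture_vois()
  expect_gt(sum(vois$target$data), 0)
  expect_gt(sum(vois$reference$data), 0)
  idffd <- ffd_identity(test_grid(), 24)
  moved <- apply_transform(vois$target, idffd, test_grid())
  expect_identical(moved$data, vois$target$data)
})

test_that("deformation amplitude is validated against the grid extent", {
  expect_error(phantom_spec(deformation = list(type = "ffd", spacing = 30,
                                               amplitude = 50)),
               "amplitude")
})
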
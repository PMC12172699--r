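test_that("write/read round-trip preserves data bit-exactly and affine", {
  set.seed(7)
  aff <- diag(c(2, 2.5, 3, 1))
  aff[1:3, 4] <- c(-31, -40, -20)
  # float32-representable data must round-trip bit-exactly
  f32 <- function(x) readBin(writeBin(as.vector(x), raw(), size = 4),
                             "double", n = length(x), size = 4)
  v <- pet_volume(array(f32(runif(16^3)), c(16, 16, 16)), aff)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_volume(v, p)
  v2 <- read_volume(p)
  expect_identical(v2$data, v$data)
  expect_lt(max(abs(v$affine - v2$affine)), 1e-4)
})

test_that("header intensity scaling is applied on read", {
  # independent oracle: raw NIfTI-1 header written byte-by-byte
  p <- withr::local_tempfile(fileext = ".nii")
  write_raw_nii(p, array(3L, c(4, 4, 4)), slope = 2, inter = 1)
  v <- read_volume(p)
  expect_equal(unique(as.vector(v$data)), 7)  # 3 * 2 + 1
})

test_that("malformed and over-dimensioned inputs are rejected", {
  p <- withr::local_tempfile(fileext = ".nii")
  writeLines("this is not an image", p)
  expect_error(read_volume(p), "NIfTI")

  p4 <- withr::local_tempfile(fileext = ".nii.gz")
  img <- RNifti::asNifti(array(1, c(4, 4, 4, 3)))
  RNifti::writeNifti(img, p4)
  expect_error(read_volume(p4), "3-D|frame")

  expect_error(read_volume(file.path(tempdir(), "nope.nii")), "not found")
})

test_that("anisotropic voxel sizes survive the header round-trip", {
  v <- pet_volume(array(rnorm(8^3), c(8, 8, 8)), diag(c(1.5, 1.5, 1.5, 1)))
  p <- withr::local_tempfile(fileext = ".nii")
  write_volume(v, p)
  hdr <- RNifti::niftiHeader(p)
  expect_equal(hdr$pixdim[2:4], c(1.5, 1.5, 1.5), tolerance = 1e-6)
  expect_lt(max(abs(read_volume(p)$affine - v$affine)), 1e-4)
})

test_that("reorient_by_header updates the affine only", {
  v <- pet_volume(array(rnorm(6^3), c(6, 6, 6)), diag(4))
  expect_identical(reorient_by_header(v, diag(4))$affine, diag(4))

  tr <- diag(4); tr[1, 4] <- 10
  v2 <- reorient_by_header(v, tr)
  expect_identical(v2$data, v$data)
  w0 <- v2$affine %*% c(0, 0, 0, 1)
  expect_equal(as.numeric(w0)[1:3], c(10, 0, 0))

  # composition equals the matrix product
  th <- pi / 7
  r1 <- diag(4); r1[1:2, 1:2] <- rbind(c(cos(th), -sin(th)),
                                       c(sin(th), cos(th)))
  r2 <- diag(4); r2[2:3, 2:3] <- rbind(c(cos(th), -sin(th)),
                                       c(sin(th), cos(th)))
  a <- reorient_by_header(reorient_by_header(v, r1), r2)$affine
  expect_equal(a, (r2 %*% r1) %*% v$affine, tolerance = 1e-12)

  sheared <- diag(4); sheared[1, 2] <- 0.3
  expect_error(reorient_by_header(v, sheared), "rigid")
})

test_that("resampling: identity, constants, and closed-form tent weights", {
  v <- pet_volume(array(runif(10^3), c(10, 10, 10)), diag(4))
  same <- resample_to(v, as_grid(v))
  expect_lt(max(abs(same$data - v$data)) / diff(range(v$data)), 1e-6)

  cv <- pet_volume(array(5.5, c(10, 10, 10)), diag(4))
  g2 <- grid_spec(c(9, 9, 9), {a <- diag(4); a[1:3, 4] <- 0.3; a})
  rc <- resample_to(cv, g2)
  expect_true(all(abs(rc$data[rc$meta$validity] - 5.5) < 1e-12))

  # impulse upsampled 2x: trilinear values are the tent-function products
  imp <- array(0, c(5, 5, 5)); imp[3, 3, 3] <- 1
  vi <- pet_volume(imp, diag(4))
  gu <- grid_spec(c(9, 9, 9), diag(c(0.5, 0.5, 0.5, 1)))
  ru <- resample_to(vi, gu)
  # at target voxel (4,4,4) 0-based -> source (2,2,2): the impulse itself
  expect_equal(ru$data[5, 5, 5], 1)
  # half-voxel offsets pick up products of 0.5 tent weights
  expect_equal(ru$data[6, 5, 5], 0.5)
  expect_equal(ru$data[6, 6, 5], 0.25)
  expect_equal(ru$data[6, 6, 6], 0.125)

  expect_error(resample_to(v, grid_spec(c(0, 4, 4), diag(4))), "positive")
})

test_that("mask volumes validate their contract and stay binary", {
  expect_error(mask_volume(array(2, c(4, 4, 4)), diag(4)), "\\[0, 1\\]")
  expect_error(mask_volume(array(0.5, c(4, 4, 4)), diag(4), "binary"),
               "binary")
  expect_error(mask_volume(array(0, c(4, 4, 4)), diag(4)), "empty")
  m <- mask_volume(array(rbinom(6^3, 1, 0.4), c(6, 6, 6)), diag(4),
                   "binary")
  g2 <- grid_spec(c(5, 5, 5), {a <- diag(4); a[1:3, 4] <- 0.4; a})
  rm_ <- resample_to(m, g2, "nearest")
  expect_true(all(rm_$data %in% c(0, 1)))
  expect_identical(rm_$kind, "binary")
})
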
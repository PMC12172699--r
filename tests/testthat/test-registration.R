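test_that("NMI self-similarity is exactly 2 and independence gives ~1", {
  set.seed(3)
  x <- array(runif(64^3), c(64, 64, 64))
  expect_equal(nmi(x, x, 64)$nmi, 2, tolerance = 1e-9)

  y <- array(runif(64^3), c(64, 64, 64))
  rep_ <- nmi(x, y, 32)
  expect_lt(abs(rep_$nmi - 1), 0.02)
  # verify through the entropies themselves: MI = Hf + Hm - Hj ~ 0
  expect_lt(abs(rep_$h_fixed + rep_$h_moving - rep_$h_joint), 0.02)
})

test_that("NMI is invariant under monotone relabeling at bin resolution", {
  # discrete levels that map to distinct bins before and after relabeling:
  # the histogram is a permutation, so all entropies are unchanged
  set.seed(4)
  lv <- 0:15
  x <- array(sample(lv, 32^3, replace = TRUE), c(32, 32, 32))
  y <- array(sample(lv, 32^3, replace = TRUE,
                    prob = (1:16) / sum(1:16)), c(32, 32, 32))
  relabel <- sort(sample(0:200, 16))  # strictly increasing map
  y2 <- array(relabel[y + 1], dim(y))
  n1 <- nmi(x, y, 256)$nmi
  n2 <- nmi(x, y2, 256)$nmi
  expect_equal(n1, n2, tolerance = 1e-9)
})

test_that("NMI rejects degenerate input", {
  x <- array(runif(16^3), c(16, 16, 16))
  expect_error(nmi(x, array(1, c(16, 16, 16))), "constant")
  expect_error(nmi(x, array(runif(8^3), c(8, 8, 8))), "share a grid")
  expect_error(nmi(array(runif(8), c(2, 2, 2)),
                   array(runif(8), c(2, 2, 2))), "overlap")
})

test_that("Powell direction-set minimizer solves a rotated quadratic", {
  A <- rbind(c(4, 1, 0), c(1, 3, -1), c(0, -1, 2))
  b <- c(1, -2, 0.5)
  f <- function(x) as.numeric(t(x - b) %*% A %*% (x - b))
  res <- powell_minimize(f, c(5, 5, 5), scales = rep(4, 3), ftol = 1e-12)
  expect_lt(max(abs(res$par - b)), 1e-4)
  expect_true(res$converged)
})

test_that("registering a volume to itself returns ~identity", {
  fx <- fixture_fixed()
  tr <- register_rigid(fx, fx)
  expect_lt(max(abs(tr$meta$params[1:3])), 0.1)  # mm
  expect_lt(max(abs(tr$meta$params[4:6])), 0.1)  # degrees
  expect_gte(tr$meta$nmi_final, tr$meta$nmi_init)
})

test_that("apply_transform: identity equivalence, inverse composition, masks", {
  v <- fixture_fixed()
  idt <- affine_transform(diag(4))
  expect_equal(apply_transform(v, idt, as_grid(v))$data,
               resample_to(v, as_grid(v))$data, tolerance = 1e-12)

  vs <- render_pet(phantom_spec(burden = 0.2, seed = 1, noise_sd = 0))$volume
  tm <- diag(4); tm[1:3, 4] <- c(4.5, -2.3, 1.1)
  ti <- solve(tm)
  there <- apply_transform(vs, affine_transform(tm), as_grid(vs))
  back <- apply_transform(there, affine_transform(ti), as_grid(vs))
  core <- back$meta$validity & there$meta$validity
  rms <- sqrt(mean((back$data[core] - vs$data[core])^2))
  expect_lt(rms, 0.02 * diff(range(vs$data)))

  m <- fixture_vois()$target
  mt <- apply_transform(m, affine_transform(tm), as_grid(m))
  expect_true(all(mt$data %in% c(0, 1)))
})

test_that("FFD basics: identity lattice, single-node pull, serialization", {
  g <- test_grid()
  t0 <- ffd_identity(g, 24)
  pts <- rbind(c(0, 0, 0), c(10.3, -22.1, 5.9))
  expect_lt(max(abs(ffd_displacement(t0, pts))), 1e-9)

  # one active control point: at its own node the cubic B-spline tensor
  # weight is (2/3)^3
  t1 <- t0
  nd <- dim(t1$control)
  ci <- c(6, 6, 4)
  t1$control[ci[1], ci[2], ci[3], 1] <- 3
  node_world <- t1$origin + (ci - 1) * t1$spacing
  u <- ffd_displacement(t1, matrix(node_world, 1))
  expect_equal(u[1, 1], 3 * (2 / 3)^3, tolerance = 1e-12)
  expect_equal(u[1, 2:3], c(0, 0))

  d <- withr::local_tempdir()
  yml <- file.path(d, "t.yaml")
  save_transform(t1, yml)
  t2 <- load_transform(yml)
  expect_equal(t2$control, t1$control, tolerance = 1e-6)
  expect_equal(t2$spacing, t1$spacing)
  expect_equal(t2$origin, t1$origin, tolerance = 1e-5)

  af <- affine_transform(tm <- {m <- diag(4); m[1, 4] <- 2; m}, dof = 12L)
  ya <- file.path(d, "a.yaml")
  save_transform(af, ya)
  expect_equal(load_transform(ya)$matrix, af$matrix)
})

test_that("register_ffd validates spacing and is identity for equal images", {
  fx <- fixture_fixed()
  expect_error(register_ffd(fx, fx, grid_spacing_mm = 4), "2 voxels")
  tr <- register_ffd(fx, fx, 20, opts = list(max_iter = c(6L, 4L)))
  g <- as_grid(fx)
  pts <- vox_to_world(g$affine, grid_ijk(g$dim))
  u <- ffd_displacement(tr, pts)
  vox_mm <- 3
  expect_lte(mean(sqrt(rowSums(u^2))), 0.2 * vox_mm)
  expect_gte(tr$meta$nmi_final, tr$meta$nmi_init)
})
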
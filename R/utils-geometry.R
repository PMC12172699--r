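# Internal geometry / interpolation helpers shared by volume_io, registration
# and the phantom generator. Voxel indices are 0-based in all internal code;
# the +1 shift to R's 1-based arrays happens only at the point of array access.

# Map n x 3 matrix of 0-based voxel indices to world mm via a 4x4 affine.
vox_to_world <- function(affine, ijk) {
  ijk <- matrix(ijk, ncol = 3)
  sweep(ijk %*% t(affine[1:3, 1:3]), 2, affine[1:3, 4], "+")
}

world_to_vox <- function(affine, xyz) {
  xyz <- matrix(xyz, ncol = 3)
  inv <- solve(affine)
  sweep(xyz %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], "+")
}

# All voxel centres of a grid as an n x 3 matrix of 0-based indices,
# fastest-varying first (column-major order of the array).
grid_ijk <- function(dm) {
  cbind(
    rep.int(seq_len(dm[1]) - 1, dm[2] * dm[3]),
    rep.int(rep(seq_len(dm[2]) - 1, each = dm[1]), dm[3]),
    rep(seq_len(dm[3]) - 1, each = dm[1] * dm[2])
  )
}

# Trilinear sampling of a 3-D array at continuous 0-based voxel coordinates.
# Out-of-support points return value 0 and inside = FALSE.
trilinear_sample <- function(arr, ijk) {
  dm <- dim(arr)
  x <- ijk[, 1]; y <- ijk[, 2]; z <- ijk[, 3]
  inside <- x >= 0 & x <= dm[1] - 1 &
            y >= 0 & y <= dm[2] - 1 &
            z >= 0 & z <= dm[3] - 1
  x0 <- floor(x); y0 <- floor(y); z0 <- floor(z)
  fx <- x - x0; fy <- y - y0; fz <- z - z0
  cl <- function(v, n) pmin.int(pmax.int(v, 0), n - 1) + 1L
  x0c <- cl(x0, dm[1]); x1c <- cl(x0 + 1, dm[1])
  y0c <- cl(y0, dm[2]); y1c <- cl(y0 + 1, dm[2])
  z0c <- cl(z0, dm[3]); z1c <- cl(z0 + 1, dm[3])
  g <- function(i, j, k) arr[cbind(i, j, k)]
  v <-
    g(x0c, y0c, z0c) * (1 - fx) * (1 - fy) * (1 - fz) +
    g(x1c, y0c, z0c) * fx       * (1 - fy) * (1 - fz) +
    g(x0c, y1c, z0c) * (1 - fx) * fy       * (1 - fz) +
    g(x1c, y1c, z0c) * fx       * fy       * (1 - fz) +
    g(x0c, y0c, z1c) * (1 - fx) * (1 - fy) * fz +
    g(x1c, y0c, z1c) * fx       * (1 - fy) * fz +
    g(x0c, y1c, z1c) * (1 - fx) * fy       * fz +
    g(x1c, y1c, z1c) * fx       * fy       * fz
  v[!inside] <- 0
  list(values = v, inside = inside)
}

nearest_sample <- function(arr, ijk) {
  dm <- dim(arr)
  i <- round(ijk[, 1]); j <- round(ijk[, 2]); k <- round(ijk[, 3])
  inside <- i >= 0 & i <= dm[1] - 1 & j >= 0 & j <= dm[2] - 1 &
            k >= 0 & k <= dm[3] - 1
  v <- numeric(nrow(ijk))
  idx <- which(inside)
  v[idx] <- arr[cbind(i[idx] + 1, j[idx] + 1, k[idx] + 1)]
  list(values = v, inside = inside)
}

# Separable convolution along one axis with zero padding.
conv_axis <- function(arr, kernel, axis) {
  half <- (length(kernel) - 1L) %/% 2L
  out <- array(0, dim(arr))
  n <- dim(arr)[axis]
  idx_all <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  for (t in seq_along(kernel)) {
    off <- t - 1L - half
    src <- seq_len(n) + off
    keep <- src >= 1L & src <= n
    if (!any(keep) || kernel[t] == 0) next
    ia <- idx_all; ia[[axis]] <- which(keep)
    ib <- idx_all; ib[[axis]] <- src[keep]
    out[ia[[1]], ia[[2]], ia[[3]]] <- out[ia[[1]], ia[[2]], ia[[3]]] +
      kernel[t] * arr[ib[[1]], ib[[2]], ib[[3]]]
  }
  out
}

# Isotropic-in-world Gaussian blur; sigma given per axis in voxels.
gaussian_blur3 <- function(arr, sigma_vox) {
  sigma_vox <- rep(sigma_vox, length.out = 3)
  for (ax in 1:3) {
    s <- sigma_vox[ax]
    if (s <= 1e-8) next
    half <- max(1L, ceiling(3 * s))
    k <- exp(-((-half:half)^2) / (2 * s^2))
    k <- k / sum(k)
    arr <- conv_axis(arr, k, ax)
  }
  arr
}

# Binary erosion with a 6-connected structuring element, repeated `steps`
# times. Used to pull VOI masks away from compartment boundaries.
erode6 <- function(mask, steps = 1L) {
  m <- mask != 0
  for (s in seq_len(steps)) {
    acc <- array(TRUE, dim(m))
    for (ax in 1:3) {
      for (off in c(-1L, 1L)) {
        shifted <- shift_axis(m, off, ax, fill = FALSE)
        acc <- acc & shifted
      }
    }
    m <- m & acc
  }
  m
}

shift_axis <- function(arr, off, axis, fill = 0) {
  out <- array(fill, dim(arr))
  n <- dim(arr)[axis]
  src <- seq_len(n) + off
  keep <- src >= 1L & src <= n
  if (!any(keep)) return(out)
  ia <- list(quote(expr = ), quote(expr = ), quote(expr = ))
  ib <- ia
  ia[[axis]] <- which(keep)
  ib[[axis]] <- src[keep]
  out[ia[[1]], ia[[2]], ia[[3]]] <- arr[ib[[1]], ib[[2]], ib[[3]]]
  out
}

is_affine_matrix <- function(m) {
  is.matrix(m) && all(dim(m) == c(4, 4)) && all(is.finite(m)) &&
    abs(det(m[1:3, 1:3])) > .Machine$double.eps &&
    all(abs(m[4, ] - c(0, 0, 0, 1)) < 1e-8)
}

is_rigid_matrix <- function(m, tol = 1e-6) {
  if (!is_affine_matrix(m)) return(FALSE)
  R <- m[1:3, 1:3]
  max(abs(crossprod(R) - diag(3))) <= tol
}
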
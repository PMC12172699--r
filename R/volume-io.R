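#' In-memory 3-D PET volume
#'
#' A `pet_volume` couples a 3-D scalar intensity array with a 4x4
#' voxel-to-world affine (RAS+ millimetres, 0-based voxel indices) and a
#' free-form `meta` list carrying provenance. It is the universal image
#' currency of the package: PET scans, templates, and normalized images are
#' all `pet_volume` objects.
#'
#' @param data numeric 3-D array of intensities.
#' @param affine 4x4 homogeneous voxel-to-world matrix; must be invertible.
#' @param meta named list of provenance entries.
#' @return A `pet_volume` object.
#' @export
pet_volume <- function(data, affine = diag(4), meta = list()) {
  if (length(dim(data)) != 3)
    stop("pet_volume: 'data' must be a 3-D array, got dim ",
         paste(dim(data), collapse = "x"))
  storage.mode(data) <- "double"
  affine <- unname(as.matrix(affine))
  if (!is_affine_matrix(affine))
    stop("pet_volume: 'affine' must be an invertible 4x4 homogeneous matrix")
  structure(list(data = data, affine = affine, meta = meta),
            class = "pet_volume")
}

#' @export
print.pet_volume <- function(x, ...) {
  vs <- sqrt(colSums(x$affine[1:3, 1:3]^2))
  cat(sprintf("<pet_volume> %s voxels @ %s mm, range [%.4g, %.4g]\n",
              paste(dim(x$data), collapse = "x"),
              paste(sprintf("%.3g", vs), collapse = "x"),
              min(x$data), max(x$data)))
  invisible(x)
}

#' Binary or probabilistic VOI mask
#'
#' A `mask_volume` holds voxel weights in `[0, 1]` on an affine grid. Binary
#' masks must take values in `{0, 1}`; probabilistic masks may take any
#' weight in `[0, 1]`. A mask must be nonempty (positive total weight).
#'
#' @param data numeric 3-D array of weights in `[0, 1]`.
#' @param affine 4x4 voxel-to-world matrix.
#' @param kind `"binary"` or `"probabilistic"`.
#' @return A `mask_volume` object (also inherits `pet_volume` layout fields).
#' @export
mask_volume <- function(data, affine = diag(4),
                        kind = c("binary", "probabilistic")) {
  kind <- match.arg(kind)
  if (length(dim(data)) != 3)
    stop("mask_volume: 'data' must be a 3-D array")
  storage.mode(data) <- "double"
  if (any(data < 0 | data > 1))
    stop("mask_volume: weights must lie in [0, 1]")
  if (kind == "binary" && !all(data %in% c(0, 1)))
    stop("mask_volume: binary mask has non-{0,1} values")
  if (sum(data) <= 0)
    stop("mask_volume: mask is empty (total weight 0)")
  affine <- unname(as.matrix(affine))
  if (!is_affine_matrix(affine))
    stop("mask_volume: invalid affine")
  structure(list(data = data, affine = affine, kind = kind, meta = list()),
            class = c("mask_volume", "pet_volume"))
}

#' Grid specification
#'
#' A light-weight description of a voxel lattice: integer dimensions plus the
#' voxel-to-world affine. Any `pet_volume` can stand in for a grid.
#'
#' @param dim integer vector of length 3.
#' @param affine 4x4 voxel-to-world matrix.
#' @export
grid_spec <- function(dim, affine) {
  dim <- as.integer(dim)
  if (length(dim) != 3 || any(dim < 1))
    stop("grid_spec: need 3 positive dimensions")
  affine <- unname(as.matrix(affine))
  if (!is_affine_matrix(affine)) stop("grid_spec: invalid affine")
  structure(list(dim = dim, affine = affine), class = "grid_spec")
}

#' @rdname grid_spec
#' @param x a `pet_volume`, `mask_volume` or `grid_spec`.
#' @export
as_grid <- function(x) {
  if (inherits(x, "grid_spec")) return(x)
  if (inherits(x, "pet_volume")) return(grid_spec(dim(x$data), x$affine))
  stop("as_grid: cannot interpret object of class ",
       paste(class(x), collapse = "/"), " as a grid")
}

#' Default template grid
#'
#' The template lattice used by the non-standard pipeline: 160 x 160 x 96
#' voxels of 1.5 mm, centred on the world origin. A coarser variant
#' (64 x 64 x 48 at 3 mm) is used throughout the test-suite for speed.
#'
#' @details `default_template_grid()` returns the full-resolution lattice;
#'   `test_grid()` the coarse one. Both are centred so that the world origin
#'   falls at the grid centre, keeping phantom geometry resolution-invariant.
#' @export
default_template_grid <- function() {
  centred_grid(c(160L, 160L, 96L), 1.5)
}

#' @rdname default_template_grid
#' @export
test_grid <- function() {
  centred_grid(c(64L, 64L, 48L), 3)
}

centred_grid <- function(dm, vox) {
  aff <- diag(c(vox, vox, vox, 1))
  aff[1:3, 4] <- -vox * (dm - 1) / 2
  grid_spec(dm, aff)
}

#' Read a 3-D NIfTI-1 volume
#'
#' Reads `.nii` / `.nii.gz`, applies the header intensity scaling
#' (`scl_slope` / `scl_inter`), and takes the world affine from the sform
#' when its code is valid, falling back to the qform. Only single-frame 3-D
#' images are accepted.
#'
#' @param path path to a NIfTI-1 file.
#' @return A [pet_volume].
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file not found: ", path)
  img <- tryCatch(suppressWarnings(RNifti::readNifti(path)),
                  error = function(e)
                    stop("read_volume: not a readable NIfTI-1 file: ", path,
                         " (", conditionMessage(e), ")", call. = FALSE))
  dm <- dim(img)
  if (length(dm) > 3) {
    if (any(dm[-(1:3)] > 1))
      stop("read_volume: expected a single 3-D frame, got shape ",
           paste(dm, collapse = "x"))
    dim(img) <- dm[1:3]
  }
  if (length(dim(img)) != 3)
    stop("read_volume: expected 3-D data, got shape ",
         paste(dm, collapse = "x"))
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  attributes(aff) <- list(dim = dim(aff))
  arr <- array(as.vector(img), dim(img))
  pet_volume(arr, aff, meta = list(source = path))
}

#' Read a NIfTI-1 VOI mask
#'
#' @param path path to a NIfTI-1 mask file.
#' @param kind `"binary"` or `"probabilistic"`; binary masks are validated
#'   to contain only 0/1.
#' @return A [mask_volume].
#' @export
read_mask <- function(path, kind = c("binary", "probabilistic")) {
  kind <- match.arg(kind)
  v <- read_volume(path)
  mask_volume(v$data, v$affine, kind)
}

#' Write a volume as NIfTI-1
#'
#' Writes float32 data with the sform set from the volume affine
#' (`sform_code = 2`, aligned).
#'
#' @param vol a [pet_volume] or [mask_volume].
#' @param path output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "pet_volume"))
  vs <- sqrt(colSums(vol$affine[1:3, 1:3]^2))
  arr <- vol$data
  RNifti::pixdim(arr) <- vs
  img <- RNifti::asNifti(arr, datatype = "float")
  RNifti::sform(img) <- structure(vol$affine, code = 2L)
  RNifti::qform(img) <- structure(vol$affine, code = 2L)
  ok <- tryCatch({RNifti::writeNifti(img, path); TRUE},
                 error = function(e) FALSE)
  if (!ok || !file.exists(path))
    stop("write_volume: could not write ", path)
  invisible(path)
}

#' Rigid reorientation by header update
#'
#' Composes a rigid-body world transform with the stored affine, leaving the
#' voxel data untouched: the counterpart of updating the NIfTI sform after a
#' rigid pre-registration instead of resampling the image.
#'
#' @param vol a [pet_volume].
#' @param rigid 4x4 rigid-body matrix (orthonormal rotation block).
#' @return A [pet_volume] with affine `rigid %*% vol$affine` and identical
#'   data.
#' @export
reorient_by_header <- function(vol, rigid) {
  stopifnot(inherits(vol, "pet_volume"))
  rigid <- unname(as.matrix(rigid))
  if (!is_rigid_matrix(rigid))
    stop("reorient_by_header: matrix is not rigid-body ",
         "(rotation block not orthonormal within 1e-6)")
  out <- vol
  out$affine <- rigid %*% vol$affine
  out$meta$reoriented <- TRUE
  out
}

#' Resample a volume onto a target grid
#'
#' Pull-back resampling: every target voxel centre is mapped through both
#' affines into the source lattice and interpolated there. Voxels outside
#' the source support are set to 0 and recorded in `meta$validity` /
#' `meta$n_outside`.
#'
#' @param vol a [pet_volume] or [mask_volume].
#' @param target a `grid_spec` or any volume defining the output grid.
#' @param interpolation `"trilinear"` (intensities) or `"nearest"` (the
#'   default for binary masks, which keeps them binary).
#' @return A volume of the same class as `vol` on the target grid.
#' @export
resample_to <- function(vol, target,
                        interpolation = c("trilinear", "nearest")) {
  stopifnot(inherits(vol, "pet_volume"))
  interpolation <- match.arg(interpolation)
  g <- as_grid(target)
  if (prod(g$dim) == 0) stop("resample_to: degenerate target grid")
  M <- solve(vol$affine) %*% g$affine   # target vox -> source vox
  ijk <- grid_ijk(g$dim)
  src <- sweep(ijk %*% t(M[1:3, 1:3]), 2, M[1:3, 4], "+")
  s <- if (interpolation == "trilinear") trilinear_sample(vol$data, src)
       else nearest_sample(vol$data, src)
  arr <- array(s$values, g$dim)
  validity <- array(s$inside, g$dim)
  if (inherits(vol, "mask_volume")) {
    out <- mask_volume(arr, g$affine,
                       kind = if (interpolation == "nearest") vol$kind
                              else "probabilistic")
  } else {
    out <- pet_volume(arr, g$affine, meta = vol$meta)
  }
  out$meta$validity <- validity
  out$meta$n_outside <- sum(!validity)
  out
}
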
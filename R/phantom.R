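# Synthetic brain-like PET phantoms with known ground truth. The geometry is
# defined in world millimetres, so the same anatomy is produced at any grid
# resolution. Compartment intensities are expressed relative to the whole
# cerebellum (intensity 1), so the cortical level IS the true SUVr.

COMPARTMENTS <- c(background = 0L, white_matter = 1L, cortex = 2L,
                  cerebellum = 3L, soft_tissue = 4L, skull = 5L)

# Ellipsoid definitions (centre mm, semi-axes mm). The cerebellar blob is
# carved outside a slightly inflated cerebrum so a CSF-like gap separates it
# from the cortical ribbon, as the tentorium does.
phantom_geometry <- function() {
  list(
    head      = list(c = c(0, -5, -8),  r = c(82, 92, 62)),
    inner     = list(c = c(0, -5, -8),  r = c(82, 92, 62) * 0.93),
    cerebrum  = list(c = c(0, 10, 2),   r = c(60, 70, 48)),
    wm_core   = list(c = c(0, 10, 2),   r = c(60, 70, 48) * 0.85),
    cereb_exc = list(c = c(0, 10, 2),   r = c(60, 70, 48) * 1.06),
    cerebell  = list(c = c(0, -52, -34), r = c(24, 19, 15))
  )
}

in_ellipsoid <- function(pts, e) {
  q <- sweep(pts, 2, e$c, "-")
  q <- sweep(q, 2, e$r, "/")
  rowSums(q * q) <= 1
}

# Classify n x 3 world points into compartment labels.
classify_points <- function(pts) {
  g <- phantom_geometry()
  lab <- integer(nrow(pts))
  head <- in_ellipsoid(pts, g$head)
  inner <- in_ellipsoid(pts, g$inner)
  cerebrum <- in_ellipsoid(pts, g$cerebrum)
  core <- in_ellipsoid(pts, g$wm_core)
  cb <- in_ellipsoid(pts, g$cerebell) & !in_ellipsoid(pts, g$cereb_exc)
  lab[head & !inner] <- COMPARTMENTS[["skull"]]
  lab[inner] <- COMPARTMENTS[["soft_tissue"]]
  lab[inner & cb] <- COMPARTMENTS[["cerebellum"]]
  lab[inner & cerebrum] <- COMPARTMENTS[["cortex"]]
  lab[inner & core] <- COMPARTMENTS[["white_matter"]]
  lab
}

#' Compartment label map for the synthetic head
#'
#' Deterministic geometry: an ellipsoidal head with a skull/scalp shell, a
#' cerebral ellipsoid split into white-matter core and cortical ribbon, a
#' separate cerebellar blob (the SUVr reference region), and a soft
#' tissue/CSF filler. Each voxel carries exactly one label.
#'
#' @param grid a `grid_spec` or volume (default [test_grid()]).
#' @return A `pet_volume` whose data are integer labels (see
#'   `attr(, "labels")` on the meta entry `labels`).
#' @export
make_anatomy <- function(grid = test_grid()) {
  g <- as_grid(grid)
  if (prod(g$dim) < 32^3)
    stop("make_anatomy: grid too small (need at least 32^3 voxels)")
  pts <- vox_to_world(g$affine, grid_ijk(g$dim))
  lab <- classify_points(pts)
  miss <- setdiff(COMPARTMENTS[-1], unique(lab))
  if (length(miss))
    stop("make_anatomy: grid does not resolve all compartments")
  pet_volume(array(as.double(lab), g$dim), g$affine,
             meta = list(labels = COMPARTMENTS))
}

#' Phantom specification
#'
#' @param grid output lattice (default the 64 x 64 x 48 / 3 mm test grid;
#'   use [default_template_grid()] for full scale).
#' @param burden amyloid burden in `[0, 1]`; 0 renders the young-control
#'   anchor cortical level (SUVr 1.014), 1 the AD anchor (2.088).
#' @param tracer one of `"PiB"`, `"FBP"`, `"FMM"`, `"FBB"`, `"NAV"`;
#'   controls nonspecific white-matter binding (high for the stilbene /
#'   benzoxazole 18F tracers, low for PiB and NAV).
#' @param psf_fwhm scanner point-spread FWHM in mm (default 8).
#' @param noise_sd Gaussian noise SD as a fraction of cerebellar intensity.
#' @param deformation `NULL`, or a list `list(type = "affine", matrix =)`
#'   or `list(type = "ffd", spacing =, amplitude =, seed =)` giving the
#'   ground-truth warp applied to the anatomy before blurring.
#' @param seed RNG seed for the noise (and cohort draws).
#' @param true_suvr optional explicit cortical level overriding the burden
#'   mapping (used by [make_cohort] so negative cohorts are not truncated
#'   at the anchor mean).
#' @param skull_uptake skull/scalp shell intensity (raise to emulate
#'   FBB-like diploe uptake).
#' @export
phantom_spec <- function(grid = test_grid(), burden = 0, tracer = "PiB",
                         psf_fwhm = 8, noise_sd = 0.05, deformation = NULL,
                         seed = 1L, true_suvr = NULL, skull_uptake = 0.15) {
  if (burden < 0 || burden > 1) stop("phantom_spec: burden must be in [0, 1]")
  if (psf_fwhm < 0) stop("phantom_spec: psf_fwhm must be >= 0")
  tracer <- match.arg(tracer, c("PiB", "FBP", "FMM", "FBB", "NAV"))
  g <- as_grid(grid)
  if (!is.null(deformation) && identical(deformation$type, "ffd")) {
    ext <- min(sqrt(colSums(g$affine[1:3, 1:3]^2)) * g$dim)
    if (deformation$amplitude > ext / 10)
      stop("phantom_spec: deformation amplitude exceeds grid extent / 10")
  }
  structure(list(grid = g, burden = burden, tracer = tracer,
                 psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                 deformation = deformation, seed = as.integer(seed),
                 true_suvr = true_suvr, skull_uptake = skull_uptake),
            class = "phantom_spec")
}

# Seed-isolated evaluation: restores the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  code
}

compartment_intensities <- function(tracer, true_suvr, skull_uptake) {
  wm <- if (tracer %in% c("FBP", "FMM", "FBB")) 1.6 else 1.1
  c(background = 0, white_matter = wm, cortex = true_suvr,
    cerebellum = 1, soft_tissue = 0.25, skull = skull_uptake)
}

# Build the ground-truth warp T(x) = world -> anatomy world.
truth_deformation <- function(spec) {
  d <- spec$deformation
  if (is.null(d) || identical(d$type, "none")) return(NULL)
  if (identical(d$type, "affine")) {
    return(affine_transform(d$matrix, dof = 12L))
  }
  if (identical(d$type, "ffd")) {
    tr <- ffd_identity(spec$grid, d$spacing)
    nd <- dim(tr$control)
    disp <- with_seed(if (is.null(d$seed)) spec$seed else d$seed,
                      stats::rnorm(prod(nd)))
    tr$control <- array(disp, nd)
    # keep the boundary control points fixed so the warp vanishes smoothly
    for (ax in 1:3) {
      idx <- list(quote(expr = ), quote(expr = ), quote(expr = ), quote(expr = ))
      idx[[ax]] <- c(1L, 2L, nd[ax] - 1L, nd[ax])
      tr$control[idx[[1]], idx[[2]], idx[[3]], ] <- 0
    }
    # scale so the maximum displacement over the grid equals the requested
    # amplitude exactly (the field is linear in the control points)
    pts <- vox_to_world(spec$grid$affine, grid_ijk(spec$grid$dim))
    mx <- max(sqrt(rowSums(ffd_displacement(tr, pts)^2)))
    if (mx > 0) tr$control <- tr$control * (d$amplitude / mx)
    return(tr)
  }
  stop("phantom: unknown deformation type '", d$type, "'")
}

#' Render a synthetic PET volume with known ground truth
#'
#' Rasterizes the anatomy (optionally through a ground-truth warp, sampled
#' analytically so no interpolation error enters), applies a Gaussian PSF,
#' then adds seeded voxelwise Gaussian noise. The true SUVr is the pre-blur
#' cortical/cerebellar intensity ratio, recorded in the truth object.
#'
#' @param spec a [phantom_spec].
#' @return `list(volume = pet_volume, truth = list(...))`; the truth carries
#'   `true_suvr`, `burden`, `tracer_suvr`, `expected_weight`, the applied
#'   `deformation` transform, and the generating [voi_set] masks.
#' @export
render_pet <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  g <- spec$grid
  true_suvr <- if (!is.null(spec$true_suvr)) spec$true_suvr
               else 1.014 + spec$burden * (2.088 - 1.014)
  ints <- compartment_intensities(spec$tracer, true_suvr, spec$skull_uptake)
  pts <- vox_to_world(g$affine, grid_ijk(g$dim))
  warp <- truth_deformation(spec)
  wpts <- if (is.null(warp)) pts
          else if (inherits(warp, "affine_transform"))
            sweep(pts %*% t(warp$matrix[1:3, 1:3]), 2, warp$matrix[1:3, 4], "+")
          else pts + ffd_displacement(warp, pts)
  lab <- classify_points(wpts)
  arr <- array(ints[lab + 1L], g$dim)
  vs <- sqrt(colSums(g$affine[1:3, 1:3]^2))
  if (spec$psf_fwhm > 0)
    arr <- gaussian_blur3(arr, spec$psf_fwhm / 2.3548 / vs)
  if (spec$noise_sd > 0)
    arr <- arr + with_seed(spec$seed,
      array(stats::rnorm(length(arr), sd = spec$noise_sd), dim(arr)))
  vol <- pet_volume(arr, g$affine,
                    meta = list(phantom = TRUE, tracer = spec$tracer,
                                seed = spec$seed))
  truth <- list(true_suvr = true_suvr, burden = spec$burden,
                tracer = spec$tracer,
                expected_weight = 1 - spec$burden,
                deformation = warp,
                masks = make_voi_set(g))
  list(volume = vol, truth = truth)
}

#' VOI masks matched to the phantom anatomy
#'
#' Binary cortical-target and whole-cerebellum reference masks, eroded one
#' voxel inside their compartments to limit partial-volume contamination of
#' the measured means.
#'
#' @param grid a `grid_spec` or volume.
#' @return A [voi_set].
#' @export
make_voi_set <- function(grid = test_grid()) {
  g <- as_grid(grid)
  pts <- vox_to_world(g$affine, grid_ijk(g$dim))
  lab <- array(classify_points(pts), g$dim)
  ctx <- erode6(lab == COMPARTMENTS[["cortex"]], 1L)
  cer <- erode6(lab == COMPARTMENTS[["cerebellum"]], 1L)
  if (!any(ctx)) ctx <- lab == COMPARTMENTS[["cortex"]]
  if (!any(cer)) cer <- lab == COMPARTMENTS[["cerebellum"]]
  voi_set(mask_volume(ctx + 0, g$affine, "binary"),
          mask_volume(cer + 0, g$affine, "binary"),
          space_label = "phantom/template space")
}

#' Seeded two-class phantom cohort
#'
#' Draws pre-blur true PiB SUVr values from the Centiloid anchor
#' distributions — Normal(1.014, 0.047) for amyloid-negative subjects and
#' Normal(2.088, 0.209) for amyloid-positive subjects — links a tracer SUVr
#' through the standard-pipeline calibration line plus residual noise, and
#' (optionally) renders each subject's volume. Fully reproducible by seed.
#'
#' @param n_neg,n_pos cohort sizes.
#' @param tracer tracer id; cortical intensity renders the tracer SUVr.
#' @param seed cohort seed.
#' @param grid output lattice.
#' @param render if `FALSE`, skip volume rasterization and return truths
#'   only (fast path for regression/statistics studies).
#' @param psf_fwhm,noise_sd forwarded to [phantom_spec].
#' @param residual_sd SD of the tracer-vs-PiB link residual (default 0.06).
#' @return list of `list(volume = , truth = )`; `volume` is `NULL` when
#'   `render = FALSE`.
#' @export
make_cohort <- function(n_neg, n_pos, tracer = "PiB", seed = 1L,
                        grid = test_grid(), render = TRUE, psf_fwhm = 8,
                        noise_sd = 0.05, residual_sd = 0.06) {
  stopifnot(n_neg >= 0, n_pos >= 0)
  tracer <- match.arg(tracer, c("PiB", "FBP", "FMM", "FBB", "NAV"))
  n <- n_neg + n_pos
  draws <- with_seed(seed, {
    pib <- c(stats::rnorm(n_neg, 1.014, 0.047),
             stats::rnorm(n_pos, 2.088, 0.209))
    res <- stats::rnorm(n, 0, residual_sd)
    list(pib = pib, res = res, noise_seeds = sample.int(2^30, max(n, 1)))
  })
  cal <- registry_lookup(tracer, "standard")
  tracer_suvr <- cal$slope * draws$pib + cal$intercept +
    if (tracer == "PiB") 0 else draws$res
  masks <- if (render) make_voi_set(grid) else NULL
  out <- vector("list", n)
  for (i in seq_len(n)) {
    burden <- min(1, max(0, (draws$pib[i] - 1.014) / (2.088 - 1.014)))
    truth <- list(pib_suvr = draws$pib[i], tracer_suvr = tracer_suvr[i],
                  true_suvr = tracer_suvr[i], burden = burden,
                  positivity = if (i <= n_neg) "negative" else "positive",
                  tracer = tracer)
    vol <- NULL
    if (render) {
      sp <- phantom_spec(grid = grid, burden = burden, tracer = tracer,
                         psf_fwhm = psf_fwhm, noise_sd = noise_sd,
                         seed = draws$noise_seeds[i],
                         true_suvr = tracer_suvr[i])
      r <- render_pet(sp)
      vol <- r$volume
      truth$masks <- masks
    }
    out[[i]] <- list(volume = vol, truth = truth)
  }
  out
}
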
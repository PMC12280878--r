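#' Phantom specification
#'
#' Describes one synthetic two-modality brain phantom: an ellipsoidal brain
#' mask on a regular voxel grid with a spherical whole-tumor (WT) region and a
#' class-conditional intensity effect inside the tumor. Intensities emulate
#' skull-stripped volumes normalized to the range \[0, 1000\].
#'
#' The class effect is a mean shift of `class_label * effect_size * noise_sd`
#' added to modality 1 inside the tumor, so `effect_size` is expressed in units
#' of the voxel noise standard deviation. Modality 2 carries no class effect,
#' exercising the multiview structure of the downstream classifier.
#'
#' @param grid_shape integer triple, voxels per axis (each >= 16).
#' @param spacing voxel spacing in mm (positive triple).
#' @param brain_axes ellipsoid semi-axes in voxels.
#' @param tumor_center tumor sphere center in voxel units.
#' @param tumor_radius tumor sphere radius in voxels (>= 2).
#' @param class_label 0 or 1.
#' @param effect_size nonnegative class-conditional mean shift, in noise SDs.
#' @param noise_sd positive voxel noise SD on the \[0, 1000\] intensity scale.
#' @param seed integer RNG seed.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48L, 48L, 48L),
                         spacing = c(1, 1, 1),
                         brain_axes = c(14, 12, 10),
                         tumor_center = c(27, 25, 24),
                         tumor_radius = 5,
                         class_label = 0L,
                         effect_size = 3,
                         noise_sd = 30,
                         seed = 42L) {
  spec <- structure(list(
    grid_shape = as.integer(grid_shape), spacing = as.numeric(spacing),
    brain_axes = as.numeric(brain_axes), tumor_center = as.numeric(tumor_center),
    tumor_radius = as.numeric(tumor_radius), class_label = as.integer(class_label),
    effect_size = as.numeric(effect_size), noise_sd = as.numeric(noise_sd),
    seed = as.integer(seed)
  ), class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$grid_shape < 16L)) stopf("grid_shape must be >= 16 voxels per axis")
  if (any(spec$spacing <= 0)) stopf("spacing must be positive")
  if (spec$tumor_radius < 2) stopf("tumor_radius must be >= 2 voxels")
  if (!spec$class_label %in% c(0L, 1L)) stopf("class_label must be 0 or 1")
  if (spec$effect_size < 0) stopf("effect_size must be nonnegative")
  if (spec$noise_sd <= 0) stopf("noise_sd must be positive")
  # tumor sphere strictly inside the brain ellipsoid: conservative box bound
  ctr <- (spec$grid_shape) / 2
  rel <- abs(spec$tumor_center - ctr) + spec$tumor_radius
  if (sum((rel / spec$brain_axes)^2) >= 1) {
    stopf("tumor sphere (center %s, radius %g) is not strictly inside the brain ellipsoid",
          paste(spec$tumor_center, collapse = ","), spec$tumor_radius)
  }
  invisible(spec)
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat(sprintf("<phantom_spec> grid %s, brain axes %s, tumor r=%g at (%s), class %d, effect %g SD\n",
              paste(x$grid_shape, collapse = "x"), paste(x$brain_axes, collapse = "/"),
              x$tumor_radius, paste(x$tumor_center, collapse = ","),
              x$class_label, x$effect_size))
  invisible(x)
}

# voxel-center coordinate arrays for a grid
voxel_centers <- function(grid_shape) {
  list(x = seq_len(grid_shape[1L]) - 0.5,
       y = seq_len(grid_shape[2L]) - 0.5,
       z = seq_len(grid_shape[3L]) - 0.5)
}

#' Generate a synthetic two-modality brain phantom
#'
#' Builds the ellipsoidal brain mask and spherical WT mask on the voxel grid
#' (voxel membership by voxel-center test), fills both modality channels with a
#' smoothed Gaussian background texture (kernel SD 2 voxels, amplitude equal
#' to the noise SD) plus white noise,
#' adds a fixed tumor contrast in both channels, and adds the class-conditional
#' mean shift to modality 1 inside the tumor. Intensities are clipped to
#' \[0, 1000\]. Identical specs (including seed) give bit-identical volumes.
#'
#' @param spec a [phantom_spec()].
#' @return An object of class `voxel_volume` with fields `intensities` (list of
#'   two 3D arrays), `brain_mask`, `wt_mask` (logical 3D arrays), `spacing`.
#' @export
generate_phantom <- function(spec) {
  validate_phantom_spec(spec)
  g <- spec$grid_shape
  cc <- voxel_centers(g)
  ctr <- g / 2
  ex <- ((cc$x - ctr[1L]) / spec$brain_axes[1L])^2
  ey <- ((cc$y - ctr[2L]) / spec$brain_axes[2L])^2
  ez <- ((cc$z - ctr[3L]) / spec$brain_axes[3L])^2
  brain <- outer(outer(ex, ey, "+"), ez, "+") <= 1
  tx <- (cc$x - spec$tumor_center[1L])^2
  ty <- (cc$y - spec$tumor_center[2L])^2
  tz <- (cc$z - spec$tumor_center[3L])^2
  wt <- outer(outer(tx, ty, "+"), tz, "+") <= spec$tumor_radius^2
  wt <- wt & brain
  if (!any(wt)) stopf("declared tumor rasterized to an empty WT mask")

  nvox <- prod(g)
  vols <- with_seed(spec$seed, {
    lapply(1:2, function(ch) {
      # background texture: smoothed Gaussian field (kernel SD 2 voxels) with
      # amplitude equal to noise_sd. The texture exists to give the
      # histogram-equalized intensities spatial structure; the voxel noise SD
      # stays the dominant stochastic scale so effect_size keeps its units
      tex <- gaussian_smooth3d(array(rnorm(nvox), g), sigma = 2)
      tex <- tex / stats::sd(tex)
      v <- 500 + spec$noise_sd * tex + array(rnorm(nvox, sd = spec$noise_sd), g)
      v <- v + (if (ch == 1L) 150 else 100) * wt          # fixed tumor contrast
      if (ch == 1L) v <- v + spec$class_label * spec$effect_size * spec$noise_sd * wt
      v[!brain] <- 0
      clamp(v, 0, 1000)
    })
  })
  structure(list(intensities = vols, brain_mask = brain, wt_mask = wt,
                 spacing = spec$spacing, spec = spec),
            class = "voxel_volume")
}

#' @export
print.voxel_volume <- function(x, ...) {
  cat(sprintf("<voxel_volume> %s voxels, %d brain, %d WT, spacing %s mm\n",
              paste(dim(x$brain_mask), collapse = "x"), sum(x$brain_mask),
              sum(x$wt_mask), paste(x$spacing, collapse = "x")))
  invisible(x)
}

#' Generate a cohort of phantoms with class labels
#'
#' Draws `n` phantoms with randomized tumor centers and radii (uniform within
#' bounds that keep the tumor strictly inside the brain) and binary labels.
#' Exactly `round(n * class_balance)` subjects receive label 1 (round half to
#' even, R's `round`); label order is a seeded permutation. Each subject gets
#' its own derived seed, so the cohort is reproducible as a whole and per
#' subject.
#'
#' @param n number of subjects (>= 2).
#' @param class_balance target fraction of label-1 subjects, in (0, 1).
#' @param effect_size class-conditional tumor mean shift in noise SDs.
#' @param seed integer RNG seed.
#' @param grid_shape,noise_sd passed to [phantom_spec()].
#' @param brain_axes ellipsoid semi-axes; by default they scale with the grid
#'   (0.375, 0.33, 0.30 of the edge length).
#' @param radius_range tumor radius bounds in voxels.
#' @return A list with `volumes` (list of `voxel_volume`), `labels` (integer
#'   vector), `specs`, and `seeds`.
#' @export
generate_cohort <- function(n, class_balance = 0.5, effect_size = 3, seed = 1L,
                            grid_shape = c(32L, 32L, 32L),
                            brain_axes = NULL,
                            noise_sd = 30,
                            radius_range = c(3, 5)) {
  if (is.null(brain_axes)) brain_axes <- grid_shape * c(0.375, 0.33, 0.3)
  if (n < 2L) stopf("a cohort needs at least 2 subjects (one per class); got n=%d", n)
  if (class_balance <= 0 || class_balance >= 1) stopf("class_balance must be in (0,1)")
  n1 <- round(n * class_balance)
  if (n1 < 1L || n1 > n - 1L) {
    stopf("n=%d with class_balance=%g leaves a class empty", n, class_balance)
  }
  labels <- with_seed(seed, sample(c(rep(1L, n1), rep(0L, n - n1))))
  seeds <- derive_seeds(seed + 1L, n)
  # a tumor of radius r fits strictly inside the ellipsoid only if
  # sum((r/axes)^2) < 1 even at the center; clamp the draw range accordingly
  r_feas <- 0.95 / sqrt(sum(1 / brain_axes^2))
  if (radius_range[1L] > r_feas) {
    stopf("radius_range[1]=%g cannot fit inside brain axes (%s); max feasible ~%.2f",
          radius_range[1L], paste(signif(brain_axes, 3), collapse = ","), r_feas)
  }
  radius_range[2L] <- min(radius_range[2L], r_feas)
  draws <- with_seed(seed + 2L, {
    r <- runif(n, radius_range[1L], radius_range[2L])
    ctr <- grid_shape / 2
    # center draw: uniform in the shrunken ellipsoid box, retried until the
    # strict-containment invariant holds (feasible by the radius clamp above)
    centers <- matrix(NA_real_, n, 3L)
    for (i in seq_len(n)) {
      tries <- 0L
      repeat {
        u <- runif(3L, -1, 1)
        cand <- ctr + u * pmax(brain_axes - r[i] - 1, 0)
        if (sum(((abs(cand - ctr) + r[i]) / brain_axes)^2) < 1) break
        tries <- tries + 1L
        if (tries > 10000L) stopf("internal error: tumor placement did not converge")
      }
      centers[i, ] <- cand
    }
    list(r = r, centers = centers)
  })
  specs <- lapply(seq_len(n), function(i) {
    phantom_spec(grid_shape = grid_shape, brain_axes = brain_axes,
                 tumor_center = draws$centers[i, ], tumor_radius = draws$r[i],
                 class_label = labels[i], effect_size = effect_size,
                 noise_sd = noise_sd, seed = seeds[i])
  })
  volumes <- lapply(specs, generate_phantom)
  list(volumes = volumes, labels = labels, specs = specs, seeds = seeds)
}

#' Write a phantom to NIfTI files plus a manifest row
#'
#' Writes one `.nii.gz` per modality and per mask under `dir` with the given
#' subject id prefix.
#'
#' @param volume a `voxel_volume`.
#' @param dir output directory (created if missing).
#' @param subject_id file name prefix.
#' @return Invisibly, a named character vector of the file paths written.
#' @export
write_phantom_nifti <- function(volume, dir, subject_id) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    t1ce = file.path(dir, paste0(subject_id, "_ch1.nii.gz")),
    t2wi = file.path(dir, paste0(subject_id, "_ch2.nii.gz")),
    brain_mask = file.path(dir, paste0(subject_id, "_brain.nii.gz")),
    wt_mask = file.path(dir, paste0(subject_id, "_wt.nii.gz"))
  )
  pix <- volume$spacing
  wr <- function(arr, path) {
    img <- RNifti::asNifti(arr, pixdim = pix)
    RNifti::writeNifti(img, path)
  }
  wr(volume$intensities[[1L]], paths[["t1ce"]])
  wr(volume$intensities[[2L]], paths[["t2wi"]])
  wr(volume$brain_mask * 1L, paths[["brain_mask"]])
  wr(volume$wt_mask * 1L, paths[["wt_mask"]])
  invisible(paths)
}

#' Read a two-modality volume with masks from NIfTI files
#'
#' @param ch1,ch2 modality image paths (modality 2 optional, may be `NA`).
#' @param brain_mask,wt_mask mask image paths (nonzero = inside).
#' @return A `voxel_volume`.
#' @export
read_volume_nifti <- function(ch1, brain_mask, wt_mask, ch2 = NA_character_) {
  rd <- function(p) {
    img <- RNifti::readNifti(p)
    a <- array(as.numeric(img), dim(img))
    attr(a, "pixdim") <- RNifti::pixdim(img)
    a
  }
  a1 <- rd(ch1)
  ints <- list(a1)
  if (!is.na(ch2)) ints <- c(ints, list(rd(ch2)))
  bm <- rd(brain_mask) != 0
  wm <- rd(wt_mask) != 0
  if (!all(dim(bm) == dim(a1)) || !all(dim(wm) == dim(a1))) {
    stopf("image and mask dimensions disagree")
  }
  structure(list(intensities = ints, brain_mask = bm, wt_mask = wm & bm,
                 spacing = attr(a1, "pixdim")[1:3]),
            class = "voxel_volume")
}
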
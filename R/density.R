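# Histogram-equalized intensities, the tumor-weighted density, and local
# vertex masses that drive the mass-preserving transport.

# Intensity of the chosen modality at each mesh vertex: mean of the incident
# brain-mask voxels (vertices sit on voxel corners, so up to 8 neighbors).
vertex_intensity <- function(mesh, volume, modality = 1L) {
  img <- volume$intensities[[modality]]
  mask <- volume$brain_mask
  d <- dim(mask)
  lat <- mesh$vertex_lattice # 0-based corner coords; incident voxels i..i+1
  acc <- numeric(mesh$n_vertices)
  cnt <- numeric(mesh$n_vertices)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- lat[, 1L] + dx; iy <- lat[, 2L] + dy; iz <- lat[, 3L] + dz
    ok <- ix >= 1L & ix <= d[1L] & iy >= 1L & iy <= d[2L] & iz >= 1L & iz <= d[3L]
    lin <- cbind(ix[ok], iy[ok], iz[ok])
    inb <- mask[lin]
    sel <- which(ok)[inb]
    acc[sel] <- acc[sel] + img[lin[inb, , drop = FALSE]]
    cnt[sel] <- cnt[sel] + 1
  }
  if (any(cnt == 0)) stopf("internal error: mesh vertex with no incident masked voxel")
  acc / cnt
}

# Whole-tumor membership of each vertex: incident to at least one WT voxel.
vertex_wt_membership <- function(mesh, volume) {
  wt <- volume$wt_mask
  d <- dim(wt)
  lat <- mesh$vertex_lattice
  member <- logical(mesh$n_vertices)
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- lat[, 1L] + dx; iy <- lat[, 2L] + dy; iz <- lat[, 3L] + dz
    ok <- ix >= 1L & ix <= d[1L] & iy >= 1L & iy <= d[2L] & iz >= 1L & iz <= d[3L]
    sel <- which(ok)
    member[sel] <- member[sel] | wt[cbind(ix[sel], iy[sel], iz[sel])]
  }
  member
}

#' Histogram-equalized vertex intensities
#'
#' Contrast-enhanced histogram equalization: each mesh vertex receives the
#' empirical-CDF rank (256-bin, over brain-mask voxels of the chosen modality)
#' of its interpolated intensity, scaled to \[0, 1\]. A constant volume maps to
#' 1.0 everywhere.
#'
#' @param mesh a `tet_mesh` built from `volume`.
#' @param volume a `voxel_volume`.
#' @param modality modality channel index used for equalization (default 1).
#' @param bins number of histogram bins (default 256).
#' @return Per-vertex values in \[0, 1\].
#' @export
histogram_equalize <- function(mesh, volume, modality = 1L, bins = 256L) {
  if (modality > length(volume$intensities)) stopf("modality %d not present", modality)
  vox <- volume$intensities[[modality]][volume$brain_mask]
  lo <- min(vox); hi <- max(vox)
  vi <- vertex_intensity(mesh, volume, modality)
  if (hi <= lo) return(rep(1, mesh$n_vertices))
  brk <- seq(lo, hi, length.out = bins + 1L)
  cdf <- cumsum(tabulate(findInterval(vox, brk, all.inside = TRUE), bins)) / length(vox)
  cdf[findInterval(vi, brk, all.inside = TRUE)]
}

#' Tumor-weighted transport density on a tetrahedral mesh
#'
#' The density is `exp(gamma * He(v))` at vertices inside the whole-tumor
#' region and 1 elsewhere; per-tet density is the mean of the four vertex
#' densities, and the local vertex mass is `(1/4) * sum over incident tets of
#' rho(tau) |tau|`. Raising `gamma` inflates the tumor's share of the
#' transported mass, which is what enlarges the tumor in the OMT tensor.
#'
#' @param mesh a `tet_mesh`.
#' @param he per-vertex histogram-equalized intensities in \[0, 1\]
#'   (see [histogram_equalize()]).
#' @param wt_vertex logical per-vertex whole-tumor membership; alternatively
#'   pass `volume` and it is derived from the WT mask.
#' @param gamma nonnegative density exponent.
#' @param volume optional `voxel_volume` used to derive `wt_vertex`.
#' @return An object of class `density_field` with `gamma`, `he`, `wt_vertex`,
#'   `rho_vertex`, `rho_tet`, `local_mass`, and `total_mass`.
#' @export
density_from_he <- function(mesh, he, gamma, wt_vertex = NULL, volume = NULL) {
  if (gamma < 0) stopf("gamma must be nonnegative, got %g", gamma)
  if (is.null(wt_vertex)) {
    if (is.null(volume)) stopf("provide wt_vertex or volume")
    wt_vertex <- vertex_wt_membership(mesh, volume)
  }
  stopifnot(length(he) == mesh$n_vertices, length(wt_vertex) == mesh$n_vertices)
  rho_v <- ifelse(wt_vertex, exp(gamma * he), 1)
  tt <- mesh$tets
  rho_t <- (rho_v[tt[, 1L]] + rho_v[tt[, 2L]] + rho_v[tt[, 3L]] + rho_v[tt[, 4L]]) / 4
  contrib <- rho_t * mesh$tet_volumes / 4
  lm <- numeric(mesh$n_vertices)
  for (s in 1:4) {
    add <- rowsum(contrib, tt[, s], reorder = FALSE)
    lm[as.integer(rownames(add))] <- lm[as.integer(rownames(add))] + add[, 1L]
  }
  structure(list(gamma = gamma, he = he, wt_vertex = wt_vertex,
                 rho_vertex = rho_v, rho_tet = rho_t, local_mass = lm,
                 total_mass = sum(rho_t * mesh$tet_volumes)),
            class = "density_field")
}

#' Normalize a density field to total mass 4*pi/3
#'
#' Scales the density so the total mass `sum rho(tau) |tau|` equals the volume
#' of the unit ball, the feasibility requirement for a mass-preserving map
#' onto it. Density ratios are unchanged.
#'
#' @param field a `density_field`.
#' @param mesh the `tet_mesh` it was computed on.
#' @return The rescaled `density_field` (with `scale` recording the factor).
#' @export
normalize_total_mass <- function(field, mesh) {
  if (!(field$total_mass > 0)) stopf("total mass must be positive")
  target <- 4 * pi / 3
  s <- target / field$total_mass
  field$rho_vertex <- field$rho_vertex * s
  field$rho_tet <- field$rho_tet * s
  field$local_mass <- field$local_mass * s
  field$total_mass <- sum(field$rho_tet * mesh$tet_volumes)
  field$scale <- s
  field
}

#' @export
print.density_field <- function(x, ...) {
  cat(sprintf("<density_field> gamma=%g, rho in [%.4g, %.4g], total mass %.6g\n",
              x$gamma, min(x$rho_vertex), max(x$rho_vertex), x$total_mass))
  invisible(x)
}
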
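# Piecewise-linear map inversion, composition into the reference cube, and
# resampling of image intensities/labels onto the regular tensor grid.

#' Invert a piecewise-linear map at query points
#'
#' Locates each query point in the image mesh (source connectivity with the
#' map's target positions) and returns the containing tet with barycentric
#' coordinates. Points outside the image are flagged and assigned the nearest
#' candidate tet (largest minimum barycentric coordinate) with the coordinates
#' clamped to the simplex.
#'
#' @param map an `omt_map`.
#' @param query_points n x 3 matrix of points in the map's codomain.
#' @return A list with `tet` (tet indices), `bary` (n x 4), `inside` (logical),
#'   and `preimage` (n x 3 source-domain points).
#' @export
invert_piecewise_linear_map <- function(map, query_points) {
  query_points <- as.matrix(query_points)
  if (nrow(query_points) == 0L) {
    return(list(tet = integer(0), bary = matrix(0, 0, 4),
                inside = logical(0), preimage = matrix(0, 0, 3)))
  }
  if (map$folded_tets > 0L) stopf("cannot invert a map with folded tets")
  loc <- .locate_points_cpp(map$target_positions, map$mesh$tets, query_points)
  pre <- barycentric_combine(map$mesh$vertices, map$mesh$tets, loc$tet, loc$bary)
  list(tet = loc$tet, bary = loc$bary, inside = loc$inside, preimage = pre)
}

barycentric_combine <- function(values, tets, tet_idx, bary) {
  tt <- tets[tet_idx, , drop = FALSE]
  out <- 0
  for (s in 1:4) {
    v <- values[tt[, s], , drop = FALSE]
    out <- out + v * bary[, s]
  }
  out
}

#' Compose the brain map with the inverse cube map
#'
#' Realizes `fhat = (f*)^(-1) o f*_rho`: each brain-mesh vertex is carried to
#' the ball by the mass-preserving map and pulled back into the reference cube
#' through the inverse of the volume-preserving cube map. Ball radii are
#' matched between the two maps before inversion (both maps carry their own
#' calibrated discrete-sphere radius).
#'
#' @param brain_map `omt_map` from [solve_mass_preserving_map()].
#' @param cube_map `omt_map` from [solve_volume_preserving_cube_map()].
#' @return An object of class `omt_composed`: the brain mesh connectivity with
#'   `positions` in the cube, plus `clamped` (count of vertices that fell
#'   outside the cube-map image and were clamped) and `cube_side`.
#' @export
compose_to_cube <- function(brain_map, cube_map) {
  if (brain_map$folded_tets > 0L || cube_map$folded_tets > 0L) {
    stopf("cannot compose maps with folded tets")
  }
  if (!brain_map$converged) {
    warning(sprintf("brain map exceeded its tolerance (max residual %.3g > %.3g); composing anyway",
                    brain_map$max_residual, brain_map$tol))
  }
  if (!cube_map$converged) {
    warning(sprintf("cube map exceeded its tolerance (max residual %.3g > %.3g); composing anyway",
                    cube_map$max_residual, cube_map$tol))
  }
  pts <- brain_map$target_positions * (cube_map$ball_radius / brain_map$ball_radius)
  inv <- invert_piecewise_linear_map(cube_map, pts)
  pos <- barycentric_combine(cube_map$mesh$vertices, cube_map$mesh$tets,
                             inv$tet, inv$bary)
  side <- cube_map$mesh$cube_side
  pos <- clamp(pos, -side / 2, side / 2)
  structure(list(mesh = brain_map$mesh, positions = pos,
                 clamped = sum(!inv$inside), cube_side = side,
                 gamma = brain_map$gamma %||% NA_real_,
                 brain_map = brain_map),
            class = "omt_composed")
}

#' @export
print.omt_composed <- function(x, ...) {
  cat(sprintf("<omt_composed> %d vertices in cube (side %.4f), %d clamped\n",
              nrow(x$positions), x$cube_side, x$clamped))
  invisible(x)
}

#' Resample a transported volume onto the regular OMT tensor grid
#'
#' For each voxel center of the `m_hat^3` grid on the reference cube, locates
#' the containing tet of the composed mesh, interpolates the modality
#' intensities barycentrically from the mesh vertices, and assigns the
#' whole-tumor label when the interpolation weight of WT member vertices
#' exceeds 1/2. Grid cells outside the mesh image are background (0).
#'
#' @param composed an `omt_composed` from [compose_to_cube()].
#' @param volume the source `voxel_volume`.
#' @param m_hat tensor edge length in voxels (>= 8, default 64).
#' @param gamma density exponent recorded as provenance.
#' @return An object of class `omt_tensor` with `intensities` (list of
#'   `m_hat^3` arrays), `labels` (integer array, 1 = WT), `gamma`, `m_hat`,
#'   and `provenance` (outside-cell count, map diagnostics).
#' @export
resample_to_tensor <- function(composed, volume, m_hat = 64L, gamma = NA_real_) {
  if (m_hat < 8L) stopf("m_hat must be >= 8, got %d", m_hat)
  side <- composed$cube_side
  g <- (seq_len(m_hat) - 0.5) / m_hat * side - side / 2
  pts <- as.matrix(expand.grid(x = g, y = g, z = g))
  loc <- .locate_points_cpp(composed$positions, composed$mesh$tets, pts)
  inside <- loc$inside
  nmod <- length(volume$intensities)
  wt_v <- vertex_wt_membership(composed$mesh, volume)
  labels <- array(0L, rep(m_hat, 3L))
  tensors <- vector("list", nmod)
  for (ch in seq_len(nmod)) {
    vi <- vertex_intensity(composed$mesh, volume, ch)
    vals <- numeric(nrow(pts))
    vals[inside] <- barycentric_combine(cbind(vi), composed$mesh$tets,
                                        loc$tet[inside],
                                        loc$bary[inside, , drop = FALSE])[, 1L]
    tensors[[ch]] <- array(vals, rep(m_hat, 3L))
  }
  wt_w <- numeric(nrow(pts))
  wt_w[inside] <- barycentric_combine(cbind(as.numeric(wt_v)), composed$mesh$tets,
                                      loc$tet[inside],
                                      loc$bary[inside, , drop = FALSE])[, 1L]
  labels[array(wt_w > 0.5, rep(m_hat, 3L))] <- 1L
  structure(list(intensities = tensors, labels = labels, gamma = gamma,
                 m_hat = as.integer(m_hat),
                 provenance = list(outside_cells = sum(!inside),
                                   clamped_vertices = composed$clamped,
                                   max_mass_residual = composed$brain_map$max_residual,
                                   iterations = composed$brain_map$iterations)),
            class = "omt_tensor")
}

#' @export
print.omt_tensor <- function(x, ...) {
  cat(sprintf("<omt_tensor> %d^3, %d modalities, %d WT voxels (%.2f%%), gamma=%s\n",
              x$m_hat, length(x$intensities), sum(x$labels == 1L),
              100 * mean(x$labels == 1L), format(x$gamma)))
  invisible(x)
}

#' Whole-tumor voxel fraction of a tensor
#'
#' The share of tensor voxels labeled WT; nondecreasing in the density
#' exponent gamma on a fixed subject.
#'
#' @param tensor an `omt_tensor`.
#' @return A fraction in \[0, 1\].
#' @export
wt_fraction <- function(tensor) mean(tensor$labels == 1L)

#' Tensorize a volume through the full OMT chain
#'
#' Convenience wrapper: mesh, equalize, density at `gamma`, normalize, solve
#' the mass-preserving map, compose with the (cached) cube map, resample.
#'
#' @param volume a `voxel_volume`.
#' @param gamma density exponent (default 1.75, the training value).
#' @param m_hat tensor resolution (default 64).
#' @param cube_resolution cube-mesh resolution (default 10; see
#'   [solve_volume_preserving_cube_map()]).
#' @param tol mass-residual tolerance of the brain solve. The default 5e-2 is
#'   the operating tolerance of the tensorization pipeline: per-tet targets
#'   are rough at the whole-tumor staircase interface, which sets a discrete
#'   feasibility floor above the solver's formal 1e-2 default.
#' @param cube_tol tolerance of the (cached) cube map (default 2e-2).
#' @param modality modality used for the histogram-equalized density.
#' @return An `omt_tensor`.
#' @export
omt_tensorize <- function(volume, gamma = 1.75, m_hat = 64L,
                          cube_resolution = 10L, tol = 5e-2, cube_tol = 2e-2,
                          modality = 1L) {
  mesh <- build_tet_mesh(volume)
  he <- histogram_equalize(mesh, volume, modality = modality)
  field <- density_from_he(mesh, he, gamma = gamma, volume = volume)
  field <- normalize_total_mass(field, mesh)
  bmap <- solve_mass_preserving_map(mesh, field, tol = tol)
  cmap <- solve_volume_preserving_cube_map(cube_resolution, tol = cube_tol)
  comp <- compose_to_cube(bmap, cmap)
  resample_to_tensor(comp, volume, m_hat = m_hat, gamma = gamma)
}

#' Wrap a raw volume as a tensor without transport
#'
#' The identity tensorization: the voxel grid itself becomes the tensor and the
#' WT mask becomes the label channel. This is the fast path for classifier
#' studies where the transport stage is not under test.
#'
#' @param volume a `voxel_volume`.
#' @return An `omt_tensor` with `gamma = NA`.
#' @export
identity_tensor <- function(volume) {
  d <- dim(volume$brain_mask)
  if (length(unique(d)) != 1L) stopf("identity tensorization needs a cubic grid")
  structure(list(intensities = volume$intensities,
                 labels = array(as.integer(volume$wt_mask), d),
                 gamma = NA_real_, m_hat = d[1L],
                 provenance = list(outside_cells = 0L, mode = "identity")),
            class = "omt_tensor")
}
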
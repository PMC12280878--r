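#' Tetrahedron volume
#'
#' Unsigned volume `|det[p1-p0, p2-p0, p3-p0]| / 6` of the tetrahedron spanned
#' by four points. Used for every per-tet volume in the package, on both the
#' source mesh and map images.
#'
#' @param p0,p1,p2,p3 numeric 3-vectors.
#' @return Nonnegative volume (0 for coplanar points).
#' @export
tet_volume <- function(p0, p1, p2, p3) {
  abs(signed_tet_volume(p0, p1, p2, p3))
}

signed_tet_volume <- function(p0, p1, p2, p3) {
  a <- p1 - p0; b <- p2 - p0; c <- p3 - p0
  (a[1L] * (b[2L] * c[3L] - b[3L] * c[2L]) -
   a[2L] * (b[1L] * c[3L] - b[3L] * c[1L]) +
   a[3L] * (b[1L] * c[2L] - b[2L] * c[1L])) / 6
}

# Vectorized signed volumes for all tets given an nv x 3 position matrix.
tet_signed_volumes <- function(pos, tets) {
  p0 <- pos[tets[, 1L], , drop = FALSE]
  e1 <- pos[tets[, 2L], , drop = FALSE] - p0
  e2 <- pos[tets[, 3L], , drop = FALSE] - p0
  e3 <- pos[tets[, 4L], , drop = FALSE] - p0
  rowSums(e1 * cross3(e2, e3)) / 6
}

# 6-connected component labelling of a logical 3D mask; returns the number of
# components and a label array.
mask_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  idx_all <- which(mask)
  comp <- 0L
  strides <- c(1L, d[1L], d[1L] * d[2L])
  coord <- arrayInd(idx_all, d)
  pos <- integer(prod(d)); pos[idx_all] <- seq_along(idx_all)
  visited <- logical(length(idx_all))
  while (any(!visited)) {
    comp <- comp + 1L
    frontier <- idx_all[which(!visited)[1L]]
    visited[pos[frontier]] <- TRUE
    lab[frontier] <- comp
    while (length(frontier)) {
      nb <- integer(0)
      ci <- arrayInd(frontier, d)
      for (ax in 1:3) for (sgn in c(-1L, 1L)) {
        ok <- if (sgn < 0) ci[, ax] > 1L else ci[, ax] < d[ax]
        cand <- frontier[ok] + sgn * strides[ax]
        nb <- c(nb, cand)
      }
      nb <- unique(nb)
      nb <- nb[mask[nb]]
      nb <- nb[!visited[pos[nb]]]
      visited[pos[nb]] <- TRUE
      lab[nb] <- comp
      frontier <- nb
    }
  }
  list(n = comp, labels = lab)
}

# The six Kuhn tetrahedra of the unit cell, as corner-bit indices 0..7 with a
# globally consistent main diagonal (0,0,0)-(1,1,1); odd axis permutations have
# two vertices swapped so all signed volumes are positive.
kuhn_pattern <- function() {
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  even <- c(TRUE, FALSE, FALSE, TRUE, TRUE, FALSE)
  bits <- function(axes) {
    v <- c(0L, 0L, 0L)
    out <- integer(4); out[1L] <- 0L
    for (s in 1:3) { v[axes[s]] <- 1L; out[s + 1L] <- v[1L] + 2L * v[2L] + 4L * v[3L] }
    out
  }
  t(vapply(seq_along(perms), function(i) {
    tet <- bits(perms[[i]])
    if (!even[i]) tet[c(1L, 3L, 2L, 4L)] else tet
  }, integer(4)))
}

#' Build a tetrahedral mesh over a masked voxel volume
#'
#' Splits every brain-mask voxel into 6 tetrahedra (Kuhn subdivision with a
#' globally consistent diagonal, so the mesh is conforming across neighboring
#' voxels). Vertices are the voxel corner lattice points, in mm.
#'
#' @param volume a `voxel_volume`.
#' @param keep_largest if `TRUE`, silently keep the largest 6-connected mask
#'   component; if `FALSE` (default), a multi-component mask is an error.
#' @return An object of class `tet_mesh` with `vertices` (nv x 3, mm), `tets`
#'   (nt x 4, positively oriented), `tet_volumes`, `vertex_lattice` (0-based
#'   corner lattice coords), `tet_cell` (linear index of the source voxel),
#'   `spacing`, and `grid_shape`.
#' @export
build_tet_mesh <- function(volume, keep_largest = FALSE) {
  mask <- volume$brain_mask
  if (!any(mask)) stopf("brain mask is empty; cannot mesh")
  cmp <- mask_components(mask)
  if (cmp$n > 1L) {
    if (!keep_largest) {
      stopf("brain mask has %d connected components; expected 1 (set keep_largest=TRUE to keep the largest)",
            cmp$n)
    }
    counts <- tabulate(cmp$labels[cmp$labels > 0L], cmp$n)
    mask <- cmp$labels == which.max(counts)
  }
  d <- dim(mask)
  cells <- which(mask)
  ci <- arrayInd(cells, d) # 1-based voxel index; corners span (i-1..i, ...)
  nl <- d + 1L
  corner_key <- function(i, j, k) i + nl[1L] * (j + nl[2L] * k) # 0-based lattice
  offs <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))     # bit order: x fastest
  keys8 <- matrix(0L, length(cells), 8L)
  for (b in 1:8) {
    keys8[, b] <- corner_key(ci[, 1L] - 1L + offs[b, 1L],
                             ci[, 2L] - 1L + offs[b, 2L],
                             ci[, 3L] - 1L + offs[b, 3L])
  }
  ukeys <- sort(unique(as.vector(keys8)))
  vid8 <- matrix(match(keys8, ukeys), nrow(keys8), 8L)
  lat <- cbind(ukeys %% nl[1L],
               (ukeys %/% nl[1L]) %% nl[2L],
               ukeys %/% (nl[1L] * nl[2L]))
  verts <- sweep(lat, 2L, volume$spacing, "*")
  pat <- kuhn_pattern() + 1L
  tets <- matrix(0L, 6L * length(cells), 4L)
  for (t in 1:6) {
    tets[seq.int(t, by = 6L, length.out = length(cells)), ] <- vid8[, pat[t, ]]
  }
  tet_cell <- rep(cells, each = 6L)
  vol <- tet_signed_volumes(verts, tets)
  if (any(vol <= 0)) stopf("internal error: non-positive Kuhn tet volume")
  mesh <- structure(list(vertices = verts, tets = tets, tet_volumes = vol,
                         vertex_lattice = lat, tet_cell = tet_cell,
                         spacing = volume$spacing, grid_shape = d,
                         n_vertices = nrow(verts), n_tets = nrow(tets)),
                    class = "tet_mesh")
  total <- sum(vol)
  expect <- sum(mask) * prod(volume$spacing)
  if (abs(total - expect) > 1e-10 * expect) {
    stopf("internal error: mesh volume %g != masked voxel volume %g", total, expect)
  }
  mesh
}

#' @export
print.tet_mesh <- function(x, ...) {
  cat(sprintf("<tet_mesh> %d vertices, %d tets, total volume %.6g mm^3\n",
              x$n_vertices, x$n_tets, sum(x$tet_volumes)))
  invisible(x)
}

#' One-ring incident tetrahedra of every vertex
#'
#' @param mesh a `tet_mesh`.
#' @return A list, entry v holding the indices of the tets incident to vertex v.
#' @export
vertex_rings <- function(mesh) {
  v <- as.vector(mesh$tets)
  split(rep.int(seq_len(mesh$n_tets), 4L), v)
}

# Boundary faces: triangles appearing in exactly one tet, oriented outward.
# The four faces of tet (1,2,3,4), each ordered so that the outward normal of a
# positively oriented tet points away from the omitted vertex.
boundary_faces <- function(mesh) {
  tt <- mesh$tets
  faces <- rbind(tt[, c(2L, 3L, 4L)], tt[, c(1L, 4L, 3L)],
                 tt[, c(1L, 2L, 4L)], tt[, c(1L, 3L, 2L)])
  lo <- pmin(faces[, 1L], faces[, 2L], faces[, 3L])
  hi <- pmax(faces[, 1L], faces[, 2L], faces[, 3L])
  mid <- faces[, 1L] + faces[, 2L] + faces[, 3L] - lo - hi
  if (max(hi) >= 2^17) stopf("mesh too large for face keying (>= 2^17 vertices)")
  key <- (lo * 2^17 + mid) * 2^17 + hi # exact in doubles for nv < 2^17
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  faces[!dup, , drop = FALSE]
}

# Volume enclosed by an oriented triangle surface at the given positions
# (divergence theorem; exact for the piecewise-linear image).
enclosed_volume <- function(pos, faces) {
  a <- pos[faces[, 1L], , drop = FALSE]
  b <- pos[faces[, 2L], , drop = FALSE]
  c <- pos[faces[, 3L], , drop = FALSE]
  sum(rowSums(a * cross3(b, c))) / 6
}
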
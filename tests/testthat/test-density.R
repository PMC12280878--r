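test_that("histogram equalization produces calibrated ranks", {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- histogram_equalize(mesh, vol)
  expect_true(all(he >= 0 & he <= 1))
  # equalization property: on a smoothly varying random volume (so that the
  # vertex interpolation does not distort voxel ranks) the rank distribution
  # is near-uniform in Kolmogorov distance
  svol <- vol
  svol$intensities[[1L]] <- with_seed(17L, {
    500 + 200 * omtapc:::gaussian_smooth3d(array(rnorm(24^3), rep(24, 3L)), 2)
  })
  hes <- histogram_equalize(mesh, svol)
  ks <- suppressWarnings(stats::ks.test(hes, "punif")$statistic)
  expect_lt(unname(ks), 0.05)
  # constant input maps to all ones
  cvol <- vol
  cvol$intensities[[1L]] <- array(7, dim(vol$brain_mask))
  expect_equal(histogram_equalize(mesh, cvol), rep(1, mesh$n_vertices))
  # two-level input maps to {0.5, 1}
  tvol <- vol
  half <- array(100, dim(vol$brain_mask))
  half[seq_len(12), , ] <- 900
  tvol$intensities[[1L]] <- half
  he2 <- histogram_equalize(mesh, tvol)
  # vertices interpolated across the step take intermediate CDF values;
  # those on pure plateaus take exactly the two CDF levels
  counts <- table(round(he2, 6))
  expect_true(all(abs(sort(unique(round(he2[he2 %in% c(0.5, 1)], 6))) - c(0.5, 1)) < 1e-9))
  lv <- sort(unique(round(he2, 6)))
  expect_true(lv[1L] >= 0.4 && lv[length(lv)] == 1)
})

test_that("density field follows the tumor-weighted exponential form", {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- histogram_equalize(mesh, vol)
  f0 <- density_from_he(mesh, he, gamma = 0, volume = vol)
  expect_equal(f0$rho_vertex, rep(1, mesh$n_vertices))
  # gamma = 0: local mass is a quarter of the incident tet volume sum
  rings <- vertex_rings(mesh)
  lm_oracle <- vapply(rings, function(ts) sum(mesh$tet_volumes[ts]) / 4, numeric(1))
  expect_equal(unname(f0$local_mass), unname(lm_oracle), tolerance = 1e-12)

  f <- density_from_he(mesh, he, gamma = 1.75, volume = vol)
  wt <- f$wt_vertex
  expect_equal(f$rho_vertex[wt], exp(1.75 * he[wt]))
  expect_true(all(f$rho_vertex[!wt] == 1))
  # direct evaluation: He = 1 inside the tumor would give exp(1.75)
  expect_equal(max(f$rho_vertex) <= exp(1.75), TRUE)
  # per-tet density is the 4-vertex mean
  i <- 137L
  expect_equal(f$rho_tet[i], mean(f$rho_vertex[mesh$tets[i, ]]))
  expect_true(all(f$rho_tet >= apply(matrix(f$rho_vertex[mesh$tets], ncol = 4), 1, min) - 1e-12))
  # local mass sums equal total mass
  expect_equal(sum(f$local_mass), sum(f$rho_tet * mesh$tet_volumes), tolerance = 1e-9)
  expect_error(density_from_he(mesh, he, gamma = -1, volume = vol), "nonnegative")
})

test_that("density is pointwise nondecreasing in gamma on the tumor", {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- histogram_equalize(mesh, vol)
  gs <- c(0, 1, 1.5, 1.75, 2)
  rho <- vapply(gs, function(g) density_from_he(mesh, he, gamma = g, volume = vol)$rho_vertex,
                numeric(mesh$n_vertices))
  for (j in seq_len(length(gs) - 1L)) {
    expect_true(all(rho[, j + 1L] >= rho[, j] - 1e-12))
  }
})

test_that("mass normalization hits 4*pi/3 exactly and preserves ratios", {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- histogram_equalize(mesh, vol)
  f <- density_from_he(mesh, he, gamma = 1.75, volume = vol)
  fn <- normalize_total_mass(f, mesh)
  expect_equal(fn$total_mass, 4 * pi / 3, tolerance = 1e-12)
  i <- 11L; j <- 1201L
  expect_equal(fn$rho_vertex[i] / fn$rho_vertex[j], f$rho_vertex[i] / f$rho_vertex[j],
               tolerance = 1e-12)
  # uniform density: the scale factor is (4*pi/3)/V in closed form
  f0 <- density_from_he(mesh, he, gamma = 0, volume = vol)
  fn0 <- normalize_total_mass(f0, mesh)
  expect_equal(fn0$scale, (4 * pi / 3) / sum(mesh$tet_volumes), tolerance = 1e-12)
})
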
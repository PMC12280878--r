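# Transport solves on small fixtures; the bundled 48^3 phantom is exercised
# by the acceptance suite.

small_field <- function(gamma) {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- fixture("small_he", function() histogram_equalize(mesh, vol))
  normalize_total_mass(density_from_he(mesh, he, gamma = gamma, volume = vol), mesh)
}

# Solved at the pipeline operating tolerance (5e-2); the formal 1e-2 default
# is exercised on the uniform-density case below and by the acceptance suite.
small_map <- function(gamma = 1) {
  fixture(sprintf("small_map_%g", gamma), function() {
    solve_mass_preserving_map(small_mesh(), small_field(gamma), tol = 5e-2)
  })
}

small_cube_map <- function() {
  fixture("small_cube_map", function() solve_volume_preserving_cube_map(10L))
}

test_that("unnormalized density fields are rejected by the solver", {
  vol <- small_volume()
  mesh <- small_mesh()
  he <- histogram_equalize(mesh, vol)
  raw <- density_from_he(mesh, he, gamma = 1, volume = vol)
  expect_error(solve_mass_preserving_map(mesh, raw), "normalize")
})

test_that("uniform density on an ellipsoid is solved by a linear candidate", {
  map <- fixture("small_map_uniform", function() {
    solve_mass_preserving_map(small_mesh(), small_field(0))
  })
  expect_true(map$converged)
  expect_lte(map$max_residual, 1e-2)
  expect_identical(map$folded_tets, 0L)
  expect_equal(map$total_image_volume, 4 * pi / 3, tolerance = 1e-9)
  # discrete ball: radius 1 up to the voxel staircase excursion
  expect_lt(map$ball_radius, 1.2)
  expect_gt(map$ball_radius, 0.95)
})

test_that("the transport solve is deterministic", {
  m1 <- solve_mass_preserving_map(small_mesh(), small_field(0))
  m2 <- solve_mass_preserving_map(small_mesh(), small_field(0))
  expect_identical(m1$target_positions, m2$target_positions)
})

test_that("the objective trace is nonincreasing and image volumes calibrate", {
  map <- small_map(1)
  expect_true(all(diff(map$objective_trace) <= 1e-12))
  expect_equal(sum(abs(map$image_volumes)), 4 * pi / 3, tolerance = 1e-9)
  expect_identical(map$folded_tets, 0L)
  # mass residuals reported match a direct recomputation
  vols <- abs(omtapc:::tet_signed_volumes(map$target_positions, map$mesh$tets))
  expect_equal(max(abs(vols - map$mass_target) / map$mass_target),
               map$max_residual, tolerance = 1e-12)
})

test_that("the cube map preserves per-tet volumes into the ball", {
  cm <- small_cube_map()
  expect_true(cm$converged)
  expect_lte(cm$max_residual, cm$tol)
  expect_equal(cm$total_image_volume, 4 * pi / 3, tolerance = 1e-9)
  # cube center maps near the ball center
  ctr_idx <- which.min(rowSums(cm$mesh$vertices^2))
  expect_lte(sqrt(sum(cm$target_positions[ctr_idx, ]^2)), 0.05)
  # corners land inside the (calibrated) ball
  expect_lte(max(omtapc:::rownorm(cm$target_positions)), cm$ball_radius + 1e-9)
  # caching: second call returns the identical object
  expect_identical(solve_volume_preserving_cube_map(10L), cm)
})

test_that("piecewise-linear inversion satisfies vertex, centroid and roundtrip oracles", {
  cm <- small_cube_map()
  # image of a vertex comes back as an indicator barycentric
  vi <- 321L
  q <- cm$target_positions[vi, , drop = FALSE]
  inv <- invert_piecewise_linear_map(cm, q)
  expect_true(inv$inside[1L])
  expect_equal(sort(inv$bary[1L, ], decreasing = TRUE)[1L], 1, tolerance = 1e-9)
  expect_equal(inv$preimage[1L, ], cm$mesh$vertices[vi, ], tolerance = 1e-7)
  # centroid of an image tet has equal barycentrics
  ti <- 100L
  tet <- cm$mesh$tets[ti, ]
  ctd <- colMeans(cm$target_positions[tet, ])
  invc <- invert_piecewise_linear_map(cm, rbind(ctd))
  expect_equal(invc$bary[1L, ], rep(0.25, 4L), tolerance = 1e-9)
  # roundtrip oracle on random interior points (safely inside the discrete
  # ball: its boundary puckers inward by up to a mesh cell at the cube edges)
  with_seed(21L, {
    u <- matrix(rnorm(3000), 1000L, 3L)
    u <- u / omtapc:::rownorm(u) * runif(1000L)^(1 / 3) * 0.8
  })
  inv2 <- invert_piecewise_linear_map(cm, u)
  expect_true(all(inv2$inside))
  # map the preimages forward through the PL map: must reproduce the queries
  fwd <- omtapc:::barycentric_combine(cm$target_positions, cm$mesh$tets,
                                      inv2$tet, inv2$bary)
  expect_lt(max(abs(fwd - u)), 1e-9)
  # empty query
  inv0 <- invert_piecewise_linear_map(cm, matrix(0, 0, 3))
  expect_identical(length(inv0$tet), 0L)
})

test_that("composition lands every brain vertex inside the reference cube", {
  comp <- fixture("small_comp", function() {
    compose_to_cube(small_map(1), small_cube_map())
  })
  side <- comp$cube_side
  expect_equal(side, (4 * pi / 3)^(1 / 3), tolerance = 1e-12)
  expect_true(all(abs(comp$positions) <= side / 2 + 1e-9))
  # composed tet volumes sum to the cube volume within the compounded tolerance
  vtot <- sum(abs(omtapc:::tet_signed_volumes(comp$positions, comp$mesh$tets)))
  expect_equal(vtot, 4 * pi / 3, tolerance = 2 * 5e-2)
})

test_that("self-composition of the cube map is the identity up to roundoff", {
  cm <- small_cube_map()
  comp <- compose_to_cube(cm, cm)
  expect_lt(max(abs(comp$positions - cm$mesh$vertices)), 1e-7)
  # the public brain-map interface reproduces the cached cube map bitwise on
  # the cube mesh under uniform density, so the chain is the exact identity
  mesh <- cube_mesh(10L)
  nv <- mesh$n_vertices
  f <- density_from_he(mesh, he = rep(1, nv), gamma = 0,
                       wt_vertex = rep(FALSE, nv))
  f <- normalize_total_mass(f, mesh)
  m2 <- solve_mass_preserving_map(mesh, f, tol = 2e-2)
  expect_equal(m2$target_positions, cm$target_positions, tolerance = 1e-12)
})

test_that("tensor resampling interpolates intensities and transports labels", {
  vol <- small_volume()
  comp <- fixture("small_comp", function() {
    compose_to_cube(small_map(1), small_cube_map())
  })
  tens <- resample_to_tensor(comp, vol, m_hat = 24L, gamma = 1)
  expect_identical(dim(tens$labels), rep(24L, 3L))
  expect_gt(sum(tens$labels == 1L), 0L) # WT survives transport
  expect_true(all(is.finite(tens$intensities[[1L]])))
  expect_error(resample_to_tensor(comp, vol, m_hat = 4L), "m_hat")
  # constant intensities come through the interpolation unchanged inside
  cvol <- vol
  cvol$intensities <- list(array(0.7, dim(vol$brain_mask)),
                           array(0.7, dim(vol$brain_mask)))
  tc <- resample_to_tensor(comp, cvol, m_hat = 16L, gamma = 1)
  inside <- tc$intensities[[1L]] != 0
  expect_gt(sum(inside), 0L)
  expect_equal(unique(round(tc$intensities[[1L]][inside], 9)), 0.7)
  # identical inputs give bit-identical tensors
  tens2 <- resample_to_tensor(comp, vol, m_hat = 24L, gamma = 1)
  expect_identical(tens$intensities, tens2$intensities)
})

test_that("tumor share of the tensor grows with gamma on a fixed phantom", {
  vol <- small_volume()
  cm <- small_cube_map()
  wf <- vapply(c(0.5, 1.75), function(g) {
    map <- small_map(g)
    wt_fraction(resample_to_tensor(compose_to_cube(map, cm), vol,
                                   m_hat = 24L, gamma = g))
  }, numeric(1))
  expect_gt(wf[2L], wf[1L])
})
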
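rand_tensor <- function(m, seed = 1L) with_seed(seed, array(rnorm(m^3), rep(m, 3L)))

test_that("mode unfoldings preserve entries, norms and fold back exactly", {
  tt <- array(1:8, c(2, 2, 2))
  for (s in 1:3) {
    u <- mode_unfold(tt, s)
    expect_identical(dim(u), c(2L, 4L))
    expect_identical(sort(as.vector(u)), 1:8)
    expect_equal(sum(u^2), sum(tt^2))
  }
  # row i of the s-mode unfolding is the slice fixing index s at i
  expect_equal(mode_unfold(tt, 1)[1L, ], as.vector(tt[1L, , ]))
  expect_equal(mode_unfold(tt, 2)[2L, ], as.vector(tt[, 2L, ]))
  expect_equal(mode_unfold(tt, 3)[1L, ], as.vector(tt[, , 1L]))
  a <- rand_tensor(7L, seed = 5L)
  for (s in 1:3) {
    expect_equal(mode_fold(mode_unfold(a, s), s), a)
    expect_equal(sum(mode_unfold(a, s)^2), sum(a^2), tolerance = 1e-12)
  }
  expect_error(mode_unfold(a, 4), "mode")
})

test_that("rank-1 tensors unfold to rank-1 matrices", {
  with_seed(2L, {
    a <- rnorm(6); b <- rnorm(6); c <- rnorm(6)
  })
  tt <- outer(outer(a, b), c)
  for (s in 1:3) {
    expect_equal(qr(mode_unfold(tt, s))$rank, 1L)
  }
})

test_that("svd features obey the Eckart-Young identity against a full-SVD oracle", {
  m <- 12L
  Ts <- matrix(with_seed(3L, rnorm(m * m^2)), m, m^2)
  sv <- svd(Ts) # oracle
  for (j in c(1L, 4L, m - 1L)) {
    x <- svd_feature(Ts, j)
    expect_length(x, m * j)
    # feature magnitude: ||vec(U_j S_j)||^2 = sum of leading singular values^2
    expect_equal(sum(x^2), sum(sv$d[seq_len(j)]^2), tolerance = 1e-10)
    # reconstruction residual equals the tail energy
    Uj <- sv$u[, seq_len(j), drop = FALSE]
    Vj <- sv$v[, seq_len(j), drop = FALSE]
    recon <- Uj %*% diag(sv$d[seq_len(j)], j, j) %*% t(Vj)
    expect_equal(sum((Ts - recon)^2), sum(sv$d[-seq_len(j)]^2), tolerance = 1e-8)
  }
  # rank-1 case: the single feature column has norm sigma
  u <- with_seed(4L, rnorm(m)); v <- with_seed(5L, rnorm(m^2))
  u <- u / sqrt(sum(u^2)); v <- v / sqrt(sum(v^2))
  x1 <- svd_feature(3.7 * u %*% t(v), 1L)
  expect_equal(sqrt(sum(x1^2)), 3.7, tolerance = 1e-10)
  expect_error(svd_feature(Ts, m), "rank")
})

test_that("svd feature signs are fixed deterministically", {
  m <- 10L
  Ts <- matrix(with_seed(6L, rnorm(m^3)), m, m^2)
  x <- svd_feature(Ts, 3L)
  # flipping input signs of singular vectors cannot change the feature
  expect_equal(svd_feature(Ts, 3L), x)
  U <- matrix(x, m, 3L)
  for (c in 1:3) expect_gt(U[which.max(abs(U[, c])), c], 0)
})

test_that("class-balanced weighting gives unit mass per class", {
  m <- 6L; j <- 2L
  feats <- lapply(1:7, function(i) mode_features(rand_tensor(m, seed = i), j = j))
  labels <- c(0L, 0L, 0L, 0L, 1L, 1L, 1L)
  wm <- build_weighted_matrices(feats, labels)
  expect_equal(sum(wm$d_i[labels == 0L]), 1)
  expect_equal(sum(wm$d_i[labels == 1L]), 1)
  expect_identical(dim(wm$X), c(3L * m * j, 7L))
  # class-1 column mass of Y is invariant under duplicating class-1 subjects
  wm2 <- build_weighted_matrices(c(feats, feats[labels == 1L]),
                                 c(labels, rep(1L, 3L)))
  expect_equal(rowSums(wm$Y), rowSums(wm2$Y), tolerance = 1e-12)
  # balanced classes reduce the weighting to a global scalar
  wmb <- build_weighted_matrices(feats[c(1:3, 5:7)], c(0L, 0L, 0L, 1L, 1L, 1L))
  expect_equal(unique(wmb$d_i), 1 / 3)
  expect_error(build_weighted_matrices(feats[1:3], c(0L, 0L, 0L)), "both classes")
})

# dense generalized-eigendecomposition oracle for the MvOPLS trace problem
dense_gep_oracle <- function(X1, X2, X3, Y, k, gammas) {
  d <- nrow(X1)
  X <- rbind(X1, X2, X3)
  A <- X %*% t(Y) %*% Y %*% t(X)
  B <- matrix(0, 3 * d, 3 * d)
  for (s in 1:3) {
    Xs <- list(X1, X2, X3)[[s]]
    B[(s - 1) * d + 1:d, (s - 1) * d + 1:d] <- Xs %*% t(Xs) + gammas[s] * diag(d)
  }
  ev <- eigen(solve(B, A))
  ord <- order(Re(ev$values), decreasing = TRUE)[seq_len(k)]
  P <- Re(ev$vectors[, ord, drop = FALSE])
  # B-normalize columns
  for (c in seq_len(k)) P[, c] <- P[, c] / sqrt(drop(t(P[, c]) %*% B %*% P[, c]))
  list(values = Re(ev$values[ord]), P = P, A = A, B = B)
}

test_that("fit_mvopls matches a dense generalized-eigenvalue oracle on toys", {
  d <- 3L; n <- 8L
  with_seed(9L, {
    X1 <- matrix(rnorm(d * n), d, n)
    X2 <- matrix(rnorm(d * n), d, n)
    X3 <- matrix(rnorm(d * n), d, n)
  })
  Y <- rbind(rep(c(1, 0), each = 4), rep(c(0, 1), each = 4))
  gam <- c(1e-4, 1e-4, 1e-4)
  fit <- fit_mvopls(X1, X2, X3, Y, k = 2L, gammas = gam)
  orc <- dense_gep_oracle(X1, X2, X3, Y, 2L, gam)
  expect_equal(fit$eigenvalues, orc$values, tolerance = 1e-10)
  # trace objective agrees
  trace_fit <- sum(diag(t(fit$P_star) %*% orc$A %*% fit$P_star))
  trace_orc <- sum(diag(t(orc$P) %*% orc$A %*% orc$P))
  expect_equal(trace_fit, trace_orc, tolerance = 1e-10)
  # B-orthonormality of the returned projections
  expect_equal(t(fit$P_star) %*% orc$B %*% fit$P_star, diag(2), tolerance = 1e-10)
  # defaults carry the standard Tikhonov value
  expect_equal(eval(formals(fit_mvopls)$gammas), c(1e-4, 1e-4, 1e-4))
})

test_that("the fitted projections beat random B-orthonormal feasible points", {
  d <- 4L; n <- 10L
  with_seed(10L, {
    X1 <- matrix(rnorm(d * n), d, n)
    X2 <- matrix(rnorm(d * n), d, n)
    X3 <- matrix(rnorm(d * n), d, n)
  })
  Y <- rbind(c(rep(1, 5), rep(0, 5)), c(rep(0, 5), rep(1, 5)))
  gam <- rep(1e-4, 3)
  fit <- fit_mvopls(X1, X2, X3, Y, k = 2L, gammas = gam)
  Xs <- list(X1, X2, X3)
  B <- matrix(0, 3 * d, 3 * d)
  for (s in 1:3) {
    B[(s - 1) * d + 1:d, (s - 1) * d + 1:d] <- Xs[[s]] %*% t(Xs[[s]]) + gam[s] * diag(d)
  }
  XYt <- rbind(X1, X2, X3) %*% t(Y)
  obj_at <- function(P) {
    W <- solve(t(P) %*% B %*% P, t(P) %*% XYt)
    Pv <- lapply(1:3, function(s) P[(s - 1) * d + 1:d, , drop = FALSE])
    omtapc:::mvopls_objective(Pv, W, Xs, Y, gam)
  }
  ours <- obj_at(fit$P_star)
  R <- chol(B)
  worse <- with_seed(20L, vapply(1:100, function(i) {
    Z <- qr.Q(qr(matrix(rnorm(3 * d * 2), 3 * d, 2)))
    P <- backsolve(R, Z)
    obj_at(P)
  }, numeric(1)))
  expect_true(all(ours <= worse + 1e-10))
})

test_that("preclassification memorizes duplicated exemplars and is calibrated", {
  m <- 8L; j <- 2L
  t0 <- rand_tensor(m, seed = 31L)
  t1 <- rand_tensor(m, seed = 32L)
  tumors <- list()
  labels <- integer(0)
  for (i in 1:4) {
    tumors <- c(tumors, list(list(structure(list(values = t0, m = m), class = "tumor_tensor"))),
                list(list(structure(list(values = t1, m = m), class = "tumor_tensor"))))
    labels <- c(labels, 0L, 1L)
  }
  model <- apc_fit(tumors, labels, j = j, k = 2L)
  pc1 <- preclassify(model$models, list(mode_features(t1, j = j)))
  expect_identical(pc1$predicted_class, 1L)
  pc0 <- preclassify(model$models, list(mode_features(t0, j = j)))
  expect_identical(pc0$predicted_class, 0L)
  expect_equal(sum(pc1$aggregate), 1)
  expect_true(all(pc1$aggregate >= 0 & pc1$aggregate <= 1))
  expect_length(pc1$per_view, 3L) # one modality here
  # dimension mismatches are reported with the expected d
  expect_error(preclassify(model$models, list(mode_features(t1, j = 3L))), "d=16")
})

test_that("label smoothing follows the convex formula", {
  expect_equal(label_smooth(c(1, 0), 0.1, 2), c(0.95, 0.05))
  expect_equal(label_smooth(c(0, 1), 0), c(0, 1))
  y <- label_smooth(c(0, 1), 0.37)
  expect_equal(sum(y), 1)
  expect_error(label_smooth(c(1, 0), 1), "epsilon")
  expect_error(label_smooth(c(0.5, 0.5), 0.1), "one-hot")
})

test_that("crop extracts the padded WT bounding box and resamples", {
  # single WT voxel: bounding box is its 3^3 neighborhood
  labels <- array(0L, c(16, 16, 16)); labels[5, 9, 12] <- 1L
  tens <- structure(list(intensities = list(array(700, c(16, 16, 16))),
                         labels = labels, gamma = NA_real_, m_hat = 16L),
                    class = "omt_tensor")
  cr <- crop_wt_tensor(tens, m = 8L)
  expect_equal(cr$bbox, rbind(lo = c(4, 8, 11), hi = c(6, 10, 13)), ignore_attr = TRUE)
  # intensities are rescaled from the [0,1000] convention to [0,1]
  expect_equal(as.vector(cr$values), rep(0.7, 8^3), tolerance = 1e-9)
  # full-extent WT: crop is a resize of the whole tensor
  labels2 <- array(1L, c(16, 16, 16))
  grad <- array(rep(seq_len(16) * 10, times = 256), c(16, 16, 16))
  tens2 <- structure(list(intensities = list(grad), labels = labels2,
                          gamma = NA_real_, m_hat = 16L), class = "omt_tensor")
  cr2 <- crop_wt_tensor(tens2, m = 16L)
  expect_equal(cr2$bbox, rbind(lo = c(1, 1, 1), hi = c(16, 16, 16)), ignore_attr = TRUE)
  expect_equal(cr2$values[, 1L, 1L], seq_len(16) / 100, tolerance = 1e-9)
  # empty WT is an explicit error
  tens3 <- tens; tens3$labels[] <- 0L
  expect_error(crop_wt_tensor(tens3), "no WT")
})
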
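# Internal helpers shared across modules.

# Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Deterministic child seeds (kept below 2^31) for per-subject streams.
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Separable Gaussian smoothing of a 3D array (reflected boundaries), used for
# the phantom's background texture. `sigma` is in voxels.
gaussian_smooth3d <- function(a, sigma) {
  stopifnot(length(dim(a)) == 3L, sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k <- k / sum(k)
  smooth_axis <- function(arr, axis) {
    d <- dim(arr)
    n <- d[axis]
    # banded convolution matrix with reflected edges
    idx <- outer(seq_len(n), x, "+")
    idx[idx < 1L] <- 2L - idx[idx < 1L]
    idx[idx > n] <- 2L * n - idx[idx > n]
    K <- matrix(0, n, n)
    for (j in seq_along(x)) {
      K[cbind(seq_len(n), idx[, j])] <- K[cbind(seq_len(n), idx[, j])] + k[j]
    }
    perm <- switch(axis, c(1L, 2L, 3L), c(2L, 1L, 3L), c(3L, 1L, 2L))
    ap <- aperm(arr, perm)
    dp <- dim(ap)
    m <- K %*% matrix(ap, dp[1L], dp[2L] * dp[3L])
    dim(m) <- dp
    aperm(m, order(perm))
  }
  for (ax in 1:3) a <- smooth_axis(a, ax)
  a
}

# Trilinear interpolation of a 3D grid sampled at voxel centers (voxel i spans
# [i-1, i] in grid units, center at i - 1/2). `pts` are n x 3 grid-unit coords.
# Out-of-range queries are clamped to the boundary sample.
trilinear <- function(grid, pts) {
  d <- dim(grid)
  u <- sweep(pts, 2L, rep(0.5, 3L), "-") # continuous sample index, 0-based
  i0 <- floor(u)
  f <- u - i0
  acc <- numeric(nrow(pts))
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    ix <- clamp(i0[, 1L] + dx + 1, 1, d[1L])
    iy <- clamp(i0[, 2L] + dy + 1, 1, d[2L])
    iz <- clamp(i0[, 3L] + dz + 1, 1, d[3L])
    w <- (if (dx) f[, 1L] else 1 - f[, 1L]) *
      (if (dy) f[, 2L] else 1 - f[, 2L]) *
      (if (dz) f[, 3L] else 1 - f[, 3L])
    acc <- acc + w * grid[cbind(ix, iy, iz)]
  }
  acc
}

# Row-wise cross product of n x 3 matrices.
cross3 <- function(a, b) {
  cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
        a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
        a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L])
}

rownorm <- function(m) sqrt(rowSums(m^2))
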
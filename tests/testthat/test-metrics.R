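test_that("auc matches the pairwise comparison oracle and its edge cases", {
  expect_equal(auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.8, 0.9)), 1)
  expect_equal(auc(c(0, 0, 1, 1), c(0.9, 0.8, 0.2, 0.1)), 0)
  with_seed(13L, {
    labels <- rep(c(0L, 1L), 25L)
    scores <- rnorm(50)
  })
  # O(n^2) pairwise oracle, ties at 1/2
  pos <- scores[labels == 1L]; neg <- scores[labels == 0L]
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  expect_equal(auc(labels, scores), mean(cmp), tolerance = 1e-12)
  # invariance under strictly monotone transforms
  expect_equal(auc(labels, exp(3 * scores)), auc(labels, scores), tolerance = 1e-12)
  expect_warning(a <- auc(rep(1L, 5L), rnorm(5)), "one class")
  expect_true(is.na(a))
})

test_that("confusion metrics agree with the closed formulas and flag undefined cells", {
  labels <- c(1, 1, 1, 0, 0, 0, 1, 0)
  scores <- c(0.9, 0.8, 0.3, 0.4, 0.2, 0.7, 0.6, 0.1)
  m <- confusion_metrics(labels, scores, threshold = 0.5)
  expect_identical(c(m$tp, m$fp, m$tn, m$fn), c(3L, 1L, 3L, 1L))
  expect_equal(m$acc, 6 / 8)
  expect_equal(m$sens, 3 / 4)
  expect_equal(m$spec, 3 / 4)
  expect_equal(m$ppv, 3 / 4)
  expect_equal(m$npv, 3 / 4)
  expect_equal(m$f1, 2 * (3 / 4) * (3 / 4) / (3 / 4 + 3 / 4))
  expect_identical(m$tp + m$fp + m$tn + m$fn, m$n)
  # perfect classifier
  p <- confusion_metrics(c(0, 1, 0, 1), c(0.1, 0.9, 0.2, 0.8))
  for (f in c("auc", "acc", "sens", "spec", "ppv", "npv", "f1")) {
    expect_equal(p[[f]], 1)
  }
  # no positive predictions: PPV undefined, SPEC still computable
  q <- confusion_metrics(c(0, 1, 0), c(0.1, 0.2, 0.3), threshold = 0.9)
  expect_true(is.na(q$ppv))
  expect_equal(q$spec, 1)
  expect_error(confusion_metrics(numeric(0), numeric(0)), "empty")
})

test_that("dice handles identity, disjoint, partial overlap and conventions", {
  a <- array(0L, c(4, 4, 4)); a[1:2, 1, 1] <- 1L
  b <- array(0L, c(4, 4, 4)); b[2, 1, 1] <- 1L
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, b), 2 * 1 / (2 + 1))
  d <- array(0L, c(4, 4, 4)); d[4, 4, 4] <- 1L
  expect_equal(dice_coefficient(a, d), 0)
  expect_equal(dice_coefficient(array(0L, c(2, 2, 2)), array(0L, c(2, 2, 2))), 1)
  expect_equal(dice_coefficient(a, b), dice_coefficient(b, a))
  expect_error(dice_coefficient(a, array(0L, c(3, 3, 3))), "shapes")
})

test_that("hd95 matches a brute-force surface-distance oracle and is symmetric", {
  dims <- c(12, 12, 12)
  a <- array(0L, dims); a[3:5, 3:5, 3:5] <- 1L
  b <- array(0L, dims); b[5:7, 3:5, 3:5] <- 1L # shifted by 2 voxels in x
  brute <- function(ma, mb, spacing = c(1, 1, 1)) {
    surf <- function(m) {
      out <- NULL
      d <- dim(m)
      for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
        if (m[i, j, k] == 0) next
        nb <- c(
          if (i > 1) m[i - 1, j, k] else 0, if (i < d[1]) m[i + 1, j, k] else 0,
          if (j > 1) m[i, j - 1, k] else 0, if (j < d[2]) m[i, j + 1, k] else 0,
          if (k > 1) m[i, j, k - 1] else 0, if (k < d[3]) m[i, j, k + 1] else 0)
        if (length(nb) < 6 || any(nb == 0)) out <- rbind(out, c(i, j, k))
      }
      sweep(out, 2, spacing, "*")
    }
    sa <- surf(ma); sb <- surf(mb)
    dist1 <- apply(sa, 1, function(p) min(sqrt(colSums((t(sb) - p)^2))))
    dist2 <- apply(sb, 1, function(p) min(sqrt(colSums((t(sa) - p)^2))))
    unname(quantile(c(dist1, dist2), 0.95))
  }
  expect_equal(hd95(a, b), brute(a, b), tolerance = 1e-12)
  expect_equal(hd95(a, a), 0)
  expect_equal(hd95(a, b), hd95(b, a), tolerance = 1e-12)
  expect_equal(hd95(a, b, spacing = c(2, 1, 1)), brute(a, b, c(2, 1, 1)),
               tolerance = 1e-12)
  expect_warning(h <- hd95(a, array(0L, dims)), "empty")
  expect_true(is.na(h))
})

test_that("bootstrap AUC interval brackets the point estimate deterministically", {
  with_seed(5L, {
    labels <- rep(c(0L, 1L), each = 30L)
    scores <- rnorm(60, mean = labels)
  })
  ci <- auc_ci(labels, scores, n_boot = 200L, seed = 9L)
  expect_lt(ci[["lower"]], ci[["estimate"]])
  expect_gt(ci[["upper"]], ci[["estimate"]])
  expect_identical(ci, auc_ci(labels, scores, n_boot = 200L, seed = 9L))
})
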
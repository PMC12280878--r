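# Classification and segmentation evaluation metrics.

#' Area under the ROC curve
#'
#' Mann-Whitney U formulation: the fraction of (positive, negative) pairs
#' ranked correctly, ties counted 1/2. Invariant under strictly monotone
#' transforms of the scores.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores (higher = more positive).
#' @return AUC in \[0, 1\], or `NA` with a warning if only one class is
#'   present.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  if (n1 == 0L || n0 == 0L) {
    warning("AUC undefined: only one class present")
    return(NA_real_)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics at a threshold
#'
#' Predictions are `scores >= threshold`. Metrics with a zero denominator are
#' returned as `NA` (undefined), never silently 0.
#'
#' @param labels binary 0/1 vector.
#' @param scores numeric scores.
#' @param threshold decision threshold (default 0.5).
#' @return An object of class `metrics_report`: `auc, acc, sens, spec, ppv,
#'   npv, f1`, the confusion counts `tp, fp, tn, fn`, `threshold`, `n`.
#' @export
confusion_metrics <- function(labels, scores, threshold = 0.5) {
  if (length(labels) == 0L) stopf("empty input")
  stopifnot(length(labels) == length(scores), is.finite(threshold))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  n <- length(labels)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  sens <- div(tp, tp + fn)
  ppv <- div(tp, tp + fp)
  f1 <- if (!is.na(sens) && !is.na(ppv) && (ppv + sens) > 0) {
    2 * ppv * sens / (ppv + sens)
  } else NA_real_
  a <- if (sum(labels == 1L) > 0L && sum(labels == 0L) > 0L) auc(labels, scores) else NA_real_
  structure(list(auc = a, acc = (tp + tn) / n, sens = sens,
                 spec = div(tn, tn + fp), ppv = ppv, npv = div(tn, tn + fn),
                 f1 = f1, tp = tp, fp = fp, tn = tn, fn = fn,
                 threshold = threshold, n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  fm <- function(v) if (is.na(v)) "undef" else sprintf("%.4f", v)
  cat(sprintf("<metrics_report> n=%d thr=%g | AUC %s ACC %s SENS %s SPEC %s PPV %s NPV %s F1 %s\n",
              x$n, x$threshold, fm(x$auc), fm(x$acc), fm(x$sens), fm(x$spec),
              fm(x$ppv), fm(x$npv), fm(x$f1)))
  cat(sprintf("  counts TP=%d FP=%d TN=%d FN=%d\n", x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Bootstrap confidence interval for the AUC
#'
#' Percentile interval from case resampling with a fixed seed.
#'
#' @param labels,scores as in [auc()].
#' @param n_boot number of resamples (default 2000).
#' @param level confidence level (default 0.95).
#' @param seed RNG seed.
#' @return Numeric vector `c(lower, estimate, upper)`.
#' @export
auc_ci <- function(labels, scores, n_boot = 2000L, level = 0.95, seed = 1L) {
  est <- auc(labels, scores)
  n <- length(labels)
  boots <- with_seed(seed, vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, n, replace = TRUE)
    if (length(unique(labels[idx])) < 2L) return(NA_real_)
    auc(labels[idx], scores[idx])
  }, numeric(1)))
  qs <- quantile(boots, c((1 - level) / 2, 1 - (1 - level) / 2), na.rm = TRUE)
  c(lower = unname(qs[1L]), estimate = est, upper = unname(qs[2L]))
}

#' Volumetric Dice coefficient
#'
#' `2|A n B| / (|A| + |B|)`; two empty masks give 1 by convention. This is the
#' plain volumetric Dice, not a lesion-wise (per-component) variant.
#'
#' @param mask_a,mask_b logical/binary arrays of identical shape.
#' @return Dice in \[0, 1\].
#' @export
dice_coefficient <- function(mask_a, mask_b) {
  if (!all(dim(mask_a) == dim(mask_b))) stopf("mask shapes differ")
  a <- mask_a != 0; b <- mask_b != 0
  denom <- sum(a) + sum(b)
  if (denom == 0L) return(1)
  2 * sum(a & b) / denom
}

# surface voxels: masked voxels with a 6-neighbor outside the mask (or on the
# array border)
surface_voxels <- function(mask) {
  d <- dim(mask)
  interior <- array(TRUE, d)
  sh <- function(m, ax, by) {
    out <- array(FALSE, d)
    idx_src <- lapply(d, seq_len)
    idx_dst <- idx_src
    if (by > 0) { idx_dst[[ax]] <- seq.int(1L + by, d[ax]); idx_src[[ax]] <- seq.int(1L, d[ax] - by) }
    else { idx_dst[[ax]] <- seq.int(1L, d[ax] + by); idx_src[[ax]] <- seq.int(1L - by, d[ax]) }
    out[idx_dst[[1L]], idx_dst[[2L]], idx_dst[[3L]]] <-
      m[idx_src[[1L]], idx_src[[2L]], idx_src[[3L]]]
    out
  }
  m <- mask != 0
  for (ax in 1:3) for (by in c(-1L, 1L)) interior <- interior & sh(m, ax, by)
  which(m & !interior, arr.ind = TRUE)
}

#' 95th-percentile symmetric surface distance (HD95)
#'
#' Pools the directed surface-voxel distances A->B and B->A and returns the
#' 95th percentile, in mm. Plain volumetric variant (no per-lesion matching).
#'
#' @param mask_a,mask_b binary arrays of identical shape.
#' @param spacing voxel spacing in mm.
#' @return HD95 in mm, or `NA` with a warning if a mask is empty.
#' @export
hd95 <- function(mask_a, mask_b, spacing = c(1, 1, 1)) {
  if (!all(dim(mask_a) == dim(mask_b))) stopf("mask shapes differ")
  if (!any(mask_a != 0) || !any(mask_b != 0)) {
    warning("HD95 undefined: empty mask")
    return(NA_real_)
  }
  sa <- sweep(surface_voxels(mask_a), 2L, spacing, "*")
  sb <- sweep(surface_voxels(mask_b), 2L, spacing, "*")
  dmin <- function(p, q) { # rows of p -> nearest row of q
    qs <- rowSums(q^2)
    apply_chunk <- function(rows) {
      d2 <- outer(rowSums(p[rows, , drop = FALSE]^2), qs, "+") -
        2 * p[rows, , drop = FALSE] %*% t(q)
      sqrt(pmax(apply(d2, 1L, min), 0))
    }
    chunks <- split(seq_len(nrow(p)), ceiling(seq_len(nrow(p)) / 2000))
    unlist(lapply(chunks, apply_chunk), use.names = FALSE)
  }
  pooled <- c(dmin(sa, sb), dmin(sb, sa))
  unname(quantile(pooled, 0.95))
}
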
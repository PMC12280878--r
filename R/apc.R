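# Algebraic preclassification: whole-tumor tensor cropping, mode unfoldings,
# truncated-SVD features, class-balanced MvOPLS fit via a generalized
# eigenvalue problem, and test-time probability preclassification.

#' Crop the whole-tumor region of a tensor to an m^3 tumor tensor
#'
#' Takes the axis-aligned bounding box of the WT label channel, expands it by
#' one voxel on every side (clamped to the grid), and trilinearly resamples the
#' chosen modality onto an `m^3` grid. Intensities are divided by the
#' normalization ceiling (1000) so downstream features are O(1) and the
#' standard Tikhonov default (1e-4) is on the right scale.
#'
#' @param tensor an `omt_tensor` (label channel must contain at least one WT
#'   voxel).
#' @param m tumor-tensor edge length (default 32, >= 4).
#' @param modality modality channel to crop.
#' @param subject_id optional provenance string.
#' @return An object of class `tumor_tensor` with `values` (m^3 array), `m`,
#'   `modality`, `bbox`, `subject_id`.
#' @export
crop_wt_tensor <- function(tensor, m = 32L, modality = 1L, subject_id = NA_character_) {
  if (m < 4L) stopf("m must be >= 4")
  wt <- which(tensor$labels == 1L, arr.ind = TRUE)
  if (nrow(wt) == 0L) {
    stopf("tensor has no WT voxels; check the segmentation / label channel")
  }
  d <- dim(tensor$labels)
  lo <- pmax(apply(wt, 2L, min) - 1L, 1L)
  hi <- pmin(apply(wt, 2L, max) + 1L, d)
  img <- tensor$intensities[[modality]]
  # sample m points per axis across the box [lo-1, hi] in grid units
  pts <- as.matrix(expand.grid(
    x = lo[1L] - 1 + (seq_len(m) - 0.5) * (hi[1L] - lo[1L] + 1) / m,
    y = lo[2L] - 1 + (seq_len(m) - 0.5) * (hi[2L] - lo[2L] + 1) / m,
    z = lo[3L] - 1 + (seq_len(m) - 0.5) * (hi[3L] - lo[3L] + 1) / m))
  vals <- trilinear(img, pts) / 1000
  structure(list(values = array(vals, rep(m, 3L)), m = as.integer(m),
                 modality = as.integer(modality), bbox = rbind(lo = lo, hi = hi),
                 subject_id = subject_id),
            class = "tumor_tensor")
}

#' s-mode unfolding of a cubic tensor
#'
#' Row i of the s-mode unfolding is the vectorization of the slice fixing
#' index s at i; the remaining modes are taken in ascending order with the
#' first-listed varying fastest.
#'
#' @param values an m x m x m array (or a `tumor_tensor`).
#' @param s mode index, 1, 2 or 3.
#' @return An m x m^2 matrix.
#' @export
mode_unfold <- function(values, s) {
  if (inherits(values, "tumor_tensor")) values <- values$values
  if (!s %in% 1:3) stopf("mode s must be 1, 2 or 3")
  m <- dim(values)[1L]
  a <- switch(s, values, aperm(values, c(2L, 1L, 3L)), aperm(values, c(3L, 1L, 2L)))
  matrix(a, m, m * m)
}

#' Fold an s-mode unfolding back into a tensor
#'
#' Inverse of [mode_unfold()].
#'
#' @param mat an m x m^2 matrix.
#' @param s mode index.
#' @return An m x m x m array.
#' @export
mode_fold <- function(mat, s) {
  m <- nrow(mat)
  a <- array(mat, rep(m, 3L))
  switch(s, a, aperm(a, c(2L, 1L, 3L)), aperm(a, c(2L, 3L, 1L)))
}

#' Truncated-SVD feature vector of an unfolding
#'
#' Computes the rank-`j` truncated SVD `U_j S_j V_j'` of the unfolding and
#' returns `vec(U_j S_j)`, a vector of length `d = m * j`. Columns are ordered
#' by descending singular value; each left singular vector is sign-fixed so
#' that its largest-magnitude entry is positive (first such entry on ties), so
#' features are reproducible across linear-algebra backends.
#'
#' @param T_s an m x m^2 unfolding matrix.
#' @param j truncation rank, `1 <= j < m`.
#' @return A numeric vector of length `m * j`, with attributes `singular_values`
#'   (all m of them) and `j`.
#' @export
svd_feature <- function(T_s, j) {
  m <- nrow(T_s)
  if (j < 1L || j >= m) stopf("truncation rank j must satisfy 1 <= j < m (m=%d)", m)
  sv <- svd(T_s, nu = m, nv = 0L)
  U <- sv$u[, seq_len(j), drop = FALSE]
  for (c in seq_len(j)) {
    piv <- which.max(abs(U[, c]))
    if (U[piv, c] < 0) U[, c] <- -U[, c]
  }
  x <- as.vector(U %*% diag(sv$d[seq_len(j)], j, j))
  attr(x, "singular_values") <- sv$d
  attr(x, "j") <- j
  x
}

#' All three mode features of a tumor tensor
#'
#' @param tumor a `tumor_tensor` (or plain m^3 array).
#' @param j truncation rank.
#' @return An object of class `mode_features`: list of `x1, x2, x3` (each of
#'   length `d = m * j`), `j`, `d`, `m`, `singular_values`.
#' @export
mode_features <- function(tumor, j = 8L) {
  vals <- if (inherits(tumor, "tumor_tensor")) tumor$values else tumor
  m <- dim(vals)[1L]
  xs <- lapply(1:3, function(s) svd_feature(mode_unfold(vals, s), j))
  structure(list(x1 = as.numeric(xs[[1L]]), x2 = as.numeric(xs[[2L]]),
                 x3 = as.numeric(xs[[3L]]), j = as.integer(j),
                 d = as.integer(m * j), m = m,
                 singular_values = lapply(xs, attr, "singular_values")),
            class = "mode_features")
}

# labels as 2-vectors: class 0 -> e1 = (1,0), class 1 -> e2 = (0,1)
label_to_vec <- function(labels) {
  rbind(1 - labels, labels)
}

#' Class-balanced feature and label matrices
#'
#' Builds the weighted matrices of the MvOPLS fit: `X_s = [x_1(s) ... x_n(s)]
#' D_n`, stacked over the three modes into `X`, and `Y = [y_1 ... y_n] D_n`,
#' with `D_n = diag(d_i)`, `d_i = 1/n1` for class-(1,0) subjects and `1/n2`
#' for class-(0,1) subjects, so each class contributes unit total weight.
#'
#' @param features list of `mode_features`, one per subject.
#' @param labels integer vector of 0/1 class labels.
#' @return List with `X1, X2, X3` (d x n), `X` (3d x n), `Y` (2 x n),
#'   `d_i` (weights), `class_counts`.
#' @export
build_weighted_matrices <- function(features, labels) {
  n <- length(features)
  stopifnot(length(labels) == n)
  n1 <- sum(labels == 0L) # y = (1,0)
  n2 <- sum(labels == 1L) # y = (0,1)
  if (n1 == 0L || n2 == 0L) stopf("both classes must be present (n1=%d, n2=%d)", n1, n2)
  d_i <- ifelse(labels == 0L, 1 / n1, 1 / n2)
  Xs <- lapply(1:3, function(s) {
    Fm <- vapply(features, function(f) f[[paste0("x", s)]], numeric(features[[1L]]$d))
    sweep(Fm, 2L, d_i, "*")
  })
  Y <- sweep(label_to_vec(labels), 2L, d_i, "*")
  list(X1 = Xs[[1L]], X2 = Xs[[2L]], X3 = Xs[[3L]], X = do.call(rbind, Xs),
       Y = Y, d_i = d_i, class_counts = c(n1 = n1, n2 = n2))
}

#' Fit the multiview orthonormalized PLS model
#'
#' Solves `max tr(P' A P)` subject to `P' B P = I_k` with `A = X Y' Y X'` and
#' `B = blockdiag(X_s X_s' + gamma_s I_d)`, i.e. the generalized eigenvalue
#' problem of the pair `(A, B)`, and sets `W* = (P*' B P*)^{-1} P*' X Y'`.
#' Because `A` has rank at most 2 (two label rows), for `k <= 2` the
#' eigenvectors are recovered exactly from the SVD of the whitened 2-column
#' factor; larger `k` falls back to a dense symmetric eigendecomposition.
#'
#' @param X1,X2,X3 d x n weighted feature views (from
#'   [build_weighted_matrices()]).
#' @param Y 2 x n weighted label matrix.
#' @param k number of components (default 2, the rank bound of `A`).
#' @param gammas positive Tikhonov parameters, one per view (default 1e-4).
#' @return An object of class `mvopls_model` with `P_star` (3d x k), per-view
#'   blocks `P_star_views`, `W_star` (k x 2), `eigenvalues`, `k`, `d`,
#'   `gammas`, `trace_objective`.
#' @export
fit_mvopls <- function(X1, X2, X3, Y, k = 2L, gammas = c(1e-4, 1e-4, 1e-4)) {
  gammas <- rep_len(as.numeric(gammas), 3L)
  if (any(gammas <= 0)) stopf("Tikhonov parameters must be positive")
  d <- nrow(X1)
  if (k < 1L) stopf("k must be >= 1")
  if (k > 3L * d) stopf("k=%d exceeds the problem dimension 3d=%d", k, 3L * d)
  Xs <- list(X1, X2, X3)
  stopifnot(nrow(X2) == d, nrow(X3) == d, nrow(Y) == 2L)
  # Cholesky factors of the SPD diagonal blocks of B
  Rs <- lapply(1:3, function(s) {
    Bs <- tcrossprod(Xs[[s]]) + diag(gammas[s], d)
    chol(Bs)
  })
  XYt <- do.call(rbind, lapply(Xs, function(x) tcrossprod(x, Y))) # 3d x 2
  # whitened factor G = R^{-T} X Y' blockwise; A = (XY')(XY')' => whitened
  # problem is eigen of G G'
  G <- do.call(rbind, lapply(1:3, function(s) {
    backsolve(Rs[[s]], XYt[(s - 1L) * d + seq_len(d), , drop = FALSE], transpose = TRUE)
  }))
  if (k <= 2L) {
    sg <- svd(G, nu = 2L, nv = 0L)
    Z <- sg$u[, seq_len(k), drop = FALSE]
    evals <- sg$d[seq_len(k)]^2
  } else {
    eg <- eigen(tcrossprod(G), symmetric = TRUE)
    Z <- eg$vectors[, seq_len(k), drop = FALSE]
    evals <- eg$values[seq_len(k)]
  }
  # deterministic sign: largest-|entry| coordinate positive
  for (c in seq_len(k)) {
    piv <- which.max(abs(Z[, c]))
    if (Z[piv, c] < 0) Z[, c] <- -Z[, c]
  }
  P <- do.call(rbind, lapply(1:3, function(s) {
    backsolve(Rs[[s]], Z[(s - 1L) * d + seq_len(d), , drop = FALSE])
  }))
  # W* by the printed formula; P'BP = I up to roundoff but is not assumed
  PtBP <- crossprod(Z)
  W <- solve(PtBP, crossprod(P, XYt))
  dimnames(W) <- NULL
  dimnames(P) <- NULL
  views <- lapply(1:3, function(s) P[(s - 1L) * d + seq_len(d), , drop = FALSE])
  structure(list(P_star = P, P_star_views = views, W_star = W,
                 eigenvalues = evals, trace_objective = sum(evals),
                 k = as.integer(k), d = as.integer(d), gammas = gammas,
                 PtBP = PtBP),
            class = "mvopls_model")
}

#' @export
print.mvopls_model <- function(x, ...) {
  cat(sprintf("<mvopls_model> d=%d, k=%d, gammas=(%s), trace objective %.6g\n",
              x$d, x$k, paste(format(x$gammas), collapse = ", "), x$trace_objective))
  invisible(x)
}

# Eq.-style objective value, used by tests and diagnostics:
# sum_s ||Y - W' P_s' X_s||_F^2 + sum_s gamma_s ||P_s W||_F^2
mvopls_objective <- function(P_views, W, Xs, Y, gammas) {
  val <- 0
  for (s in 1:3) {
    R <- Y - crossprod(W, crossprod(P_views[[s]], Xs[[s]]))
    val <- val + sum(R^2) + gammas[s] * sum((P_views[[s]] %*% W)^2)
  }
  val
}

#' Algebraic preclassification of a test subject
#'
#' Applies `y_t(s) = W*' P*(s)' x_t(s)` for the three modes of each modality
#' (modality order: channel 1 then channel 2), giving six raw probability
#' approximations. The aggregate is the softmax of a weighted mean of the six
#' raw vectors (equal weights by default; [apc_fit()] supplies Fisher-ratio
#' view weights estimated on the training set, since uninformative views would
#' otherwise dilute the ensemble); the predicted class is its argmax, ties
#' broken toward class 0. Raw vectors are exposed unmodified (they are not
#' guaranteed to lie in the simplex).
#'
#' @param model a fitted `mvopls_model` (or a list of one model per modality).
#' @param features a `mode_features` object or list of them, one per modality.
#' @param view_weights optional nonnegative weights, one per view (3 modes x
#'   modalities, in `per_view` order); `NULL` means equal weights.
#' @return An object of class `apc_preclassification` with `per_view` (named
#'   list of six 2-vectors), `aggregate` (probability 2-vector), and
#'   `predicted_class`.
#' @export
preclassify <- function(model, features, view_weights = NULL) {
  if (inherits(features, "mode_features")) features <- list(features)
  models <- if (inherits(model, "mvopls_model")) {
    rep(list(model), length(features))
  } else model
  stopifnot(length(models) == length(features))
  per_view <- list()
  for (mod in seq_along(features)) {
    f <- features[[mod]]
    mdl <- models[[mod]]
    if (f$d != mdl$d) {
      stopf("feature dimension %d does not match model dimension d=%d", f$d, mdl$d)
    }
    for (s in 1:3) {
      y <- crossprod(mdl$W_star, crossprod(mdl$P_star_views[[s]], f[[paste0("x", s)]]))
      per_view[[sprintf("mod%d_s%d", mod, s)]] <- as.numeric(y)
    }
  }
  w <- view_weights %||% rep(1, length(per_view))
  stopifnot(length(w) == length(per_view), all(w >= 0))
  if (sum(w) <= 0) w <- rep(1, length(per_view))
  w <- w / sum(w)
  raw_mean <- Reduce(`+`, Map(`*`, per_view, as.list(w)))
  e <- exp(raw_mean - max(raw_mean))
  aggregate <- e / sum(e)
  predicted <- if (aggregate[2L] > aggregate[1L]) 1L else 0L
  structure(list(per_view = per_view, aggregate = aggregate,
                 predicted_class = predicted,
                 score = aggregate[2L]),
            class = "apc_preclassification")
}

#' @export
print.apc_preclassification <- function(x, ...) {
  cat(sprintf("<apc_preclassification> P(class1)=%.4f -> class %d (%d views)\n",
              x$aggregate[2L], x$predicted_class, length(x$per_view)))
  invisible(x)
}

#' Label smoothing
#'
#' Softens a one-hot target: `y_hat = (1 - epsilon) y + epsilon / C`.
#'
#' @param y one-hot numeric vector.
#' @param epsilon smoothing parameter in \[0, 1).
#' @param n_classes number of classes C (default `length(y)`).
#' @return Smoothed vector summing to 1.
#' @export
label_smooth <- function(y, epsilon = 0.1, n_classes = length(y)) {
  if (epsilon < 0 || epsilon >= 1) stopf("epsilon must be in [0, 1)")
  if (!isTRUE(all.equal(sort(unique(y)), c(0, 1))) || sum(y) != 1) {
    stopf("y must be one-hot")
  }
  (1 - epsilon) * y + epsilon / n_classes
}

#' Fit the APC model on a labeled set of tumor tensors
#'
#' Convenience wrapper: computes mode features per modality, builds the
#' class-balanced matrices, and fits one MvOPLS model per modality.
#'
#' @param tumor_list list of subjects; each subject is a list of
#'   `tumor_tensor`s, one per modality.
#' @param labels 0/1 integer labels.
#' @param j SVD truncation rank (default 8).
#' @param k number of MvOPLS components (default 2).
#' @param gamma_reg Tikhonov parameter (default 1e-4, applied to all views).
#' @return An object of class `apc_model` holding per-modality `mvopls_model`s
#'   and the configuration echo.
#' @export
apc_fit <- function(tumor_list, labels, j = 8L, k = 2L, gamma_reg = 1e-4) {
  n_mod <- length(tumor_list[[1L]])
  models <- vector("list", n_mod)
  view_weights <- numeric(0)
  for (mod in seq_len(n_mod)) {
    fs <- lapply(tumor_list, function(subj) mode_features(subj[[mod]], j = j))
    wm <- build_weighted_matrices(fs, labels)
    models[[mod]] <- fit_mvopls(wm$X1, wm$X2, wm$X3, wm$Y, k = k,
                                gammas = rep(gamma_reg, 3L))
    # Fisher discriminant ratio of each view on the training set: weight for
    # the aggregate so uninformative modes/modalities do not dilute it
    for (s in 1:3) {
      Fm <- vapply(fs, function(f) f[[paste0("x", s)]], numeric(fs[[1L]]$d))
      Ys <- crossprod(models[[mod]]$W_star,
                      crossprod(models[[mod]]$P_star_views[[s]], Fm)) # 2 x n
      dsc <- Ys[2L, ] - Ys[1L, ]
      m0 <- mean(dsc[labels == 0L]); m1 <- mean(dsc[labels == 1L])
      v0 <- stats::var(dsc[labels == 0L]); v1 <- stats::var(dsc[labels == 1L])
      vp <- ((sum(labels == 0L) - 1) * v0 + (sum(labels == 1L) - 1) * v1) /
        max(length(labels) - 2L, 1L)
      w_v <- (m1 - m0)^2 / (vp + 1e-12)
      # single-subject classes leave the pooled variance undefined; such a
      # view gets no discriminability evidence and weight 0
      view_weights[sprintf("mod%d_s%d", mod, s)] <- if (is.finite(w_v)) w_v else 0

    }
  }
  structure(list(models = models, n_modalities = n_mod,
                 view_weights = view_weights,
                 config = list(j = as.integer(j), k = as.integer(k),
                               gamma_reg = gamma_reg, m = tumor_list[[1L]][[1L]]$m)),
            class = "apc_model")
}

#' Preclassify a list of test subjects with a fitted APC model
#'
#' @param model an `apc_model` from [apc_fit()].
#' @param tumor_list list of subjects (lists of `tumor_tensor` per modality).
#' @return A data frame with the six raw view outputs, the aggregate
#'   probability of class 1, and the predicted class per subject.
#' @export
apc_predict <- function(model, tumor_list) {
  j <- model$config$j
  rows <- lapply(seq_along(tumor_list), function(i) {
    feats <- lapply(seq_len(model$n_modalities),
                    function(mod) mode_features(tumor_list[[i]][[mod]], j = j))
    pc <- preclassify(model$models, feats, view_weights = model$view_weights)
    raw <- unlist(pc$per_view)
    out <- c(raw, prob_class1 = pc$aggregate[2L], predicted = pc$predicted_class)
    out
  })
  df <- as.data.frame(do.call(rbind, rows))
  df$predicted <- as.integer(df$predicted)
  cbind(subject = seq_along(tumor_list), df)
}
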
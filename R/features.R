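quantile_bin <- function(x, n_bins = 8) {
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n_bins + 1),
                               names = FALSE, type = 7))
  if (length(br) < 2) return(rep(1L, length(x)))   # constant feature
  cut(x, breaks = br, include.lowest = TRUE, labels = FALSE)
}

mi_discrete <- function(a, b) {
  tab <- table(a, b)
  p <- tab / sum(tab)
  px <- rowSums(p); py <- colSums(p)
  pos <- p > 0
  sum(p[pos] * log(p[pos] / outer(px, py)[pos]))
}

#' Rank features by max-relevance min-redundancy mutual information
#'
#' Greedy mRMR ranking: the first feature maximizes the mutual information
#' MI(f; y); each subsequent pick maximizes MI(f; y) minus the mean MI
#' between f and the features already picked.  MI is estimated on
#' quantile-discretized features (8 bins by default).  Constant features
#' have MI 0 and sort last; they are never an error.
#'
#' @param X Numeric matrix, subjects x features (training data only --
#'   ranking inside each CV fold is the caller's responsibility).
#' @param y Class labels (2 levels).
#' @param k Number of features to return (default 15).
#' @param n_bins Quantile bins for MI estimation (default 8).
#' @return Integer vector of column indices, best first, length
#'   `min(k, ncol(X))`.
#' @export
rank_features_mi <- function(X, y, k = 15, n_bins = 8) {
  stopifnot(is.matrix(X), nrow(X) == length(y))
  k <- min(k, ncol(X))
  D <- apply(X, 2, quantile_bin, n_bins = n_bins)
  rel <- apply(D, 2, mi_discrete, b = y)
  picked <- integer(0)
  # cache pairwise MI with picked features as we go
  red <- matrix(NA_real_, nrow = 0, ncol = ncol(X))
  for (step in seq_len(k)) {
    if (step == 1) {
      score <- rel
    } else {
      score <- rel - colMeans(red, na.rm = TRUE)
    }
    score[picked] <- -Inf
    nxt <- which.max(score)
    picked <- c(picked, nxt)
    if (step < k) {
      red <- rbind(red, vapply(seq_len(ncol(X)), function(j)
        if (j %in% picked) 0 else mi_discrete(D[, nxt], D[, j]),
        numeric(1)))
    }
  }
  picked
}

#' Consensus features across cross-validation folds
#'
#' The m features most frequently present in the folds' top-k rankings;
#' ties break by better (smaller) mean rank, then by feature id.
#'
#' @param per_fold_rankings List of ranked feature-id vectors, one per
#'   fold (best first).
#' @param m Number of consensus features (default 15).
#' @return Tibble with columns `feature`, `freq` (folds selecting it) and
#'   `mean_rank`, the top m rows.
#' @export
consensus_features <- function(per_fold_rankings, m = 15) {
  stopifnot(length(per_fold_rankings) >= 1)
  tab <- purrr::map_dfr(per_fold_rankings, function(r)
    tibble::tibble(feature = r, rank = seq_along(r)))
  agg <- tab |>
    dplyr::group_by(.data$feature) |>
    dplyr::summarise(freq = dplyr::n(), mean_rank = mean(.data$rank),
                     .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$freq), .data$mean_rank, .data$feature)
  if (m > nrow(agg)) {
    warning("only ", nrow(agg), " distinct features selected across folds; ",
            "returning all")
    m <- nrow(agg)
  }
  agg[seq_len(m), ]
}

solve_gep_smallest <- function(A, B, d, ridge = 1e-8) {
  # A u = lambda B u, B symmetric PSD; return d eigenvectors of smallest
  # lambda, columns orthonormalized
  B <- (B + t(B)) / 2 + ridge * mean(diag(B) + ridge) * diag(nrow(B))
  R <- chol(B)
  M <- t(backsolve(R, t(backsolve(R, (A + t(A)) / 2, transpose = TRUE)),
                   transpose = TRUE))
  e <- eigen((M + t(M)) / 2, symmetric = TRUE)
  idx <- order(e$values)[seq_len(d)]
  U <- backsolve(R, e$vectors[, idx, drop = FALSE])
  qr.Q(qr(U))
}

#' Fit a tensor subspace analysis (TSA) projection
#'
#' Learns row and column projection bases (N x d1, N x d2) for a set of
#' square matrices (connectivity graphs treated as second-order tensors)
#' by the alternating generalized eigenproblem of tensor subspace
#' analysis with a supervised affinity: within-class subject pairs have
#' affinity 1, between-class pairs 0, so the learned subspace keeps
#' same-class graphs close.  Bases are orthonormalized, making the d = N
#' case an exact rotation.
#'
#' @param mats List of N x N numeric matrices (training subjects only).
#' @param y Class labels, one per matrix.
#' @param d1,d2 Projection dimensions (default 6 each; at most N).
#' @param n_iter Alternating iterations (default 5).
#' @return A `tsa_projection`: list with orthonormal `U` (N x d1) and `V`
#'   (N x d2).
#' @export
tsa_fit <- function(mats, y, d1 = 6, d2 = 6, n_iter = 5) {
  stopifnot(length(mats) == length(y), length(mats) >= 2)
  N <- nrow(mats[[1]])
  stopifnot(all(vapply(mats, function(m) all(dim(m) == N), logical(1))))
  if (d1 > N || d2 > N) stop("projection dimensions cannot exceed N = ", N)
  n <- length(mats)
  S <- outer(y, y, "==") * 1
  diag(S) <- 0
  Dd <- rowSums(S)
  V <- diag(N)[, seq_len(d2), drop = FALSE]
  U <- NULL
  for (it in seq_len(n_iter)) {
    XV <- lapply(mats, function(X) X %*% V)
    Dv <- Reduce(`+`, Map(function(M, d) d * tcrossprod(M), XV, Dd))
    Sv <- matrix(0, N, N)
    for (a in seq_len(n)) for (b in seq_len(n)) if (S[a, b] > 0)
      Sv <- Sv + S[a, b] * XV[[a]] %*% t(XV[[b]])
    U <- solve_gep_smallest(Dv - Sv, Dv, d1)
    XU <- lapply(mats, function(X) t(X) %*% U)
    Du <- Reduce(`+`, Map(function(M, d) d * tcrossprod(M), XU, Dd))
    Su <- matrix(0, N, N)
    for (a in seq_len(n)) for (b in seq_len(n)) if (S[a, b] > 0)
      Su <- Su + S[a, b] * XU[[a]] %*% t(XU[[b]])
    V <- solve_gep_smallest(Du - Su, Du, d2)
  }
  structure(list(U = U, V = V, d1 = d1, d2 = d2), class = "tsa_projection")
}

#' Project graphs through a fitted TSA projection
#'
#' @param object A `tsa_projection` from [tsa_fit()].
#' @param mats List of N x N matrices to project (train or held-out).
#' @param ... Unused.
#' @return Matrix, subjects x (d1 * d2): each row is the flattened
#'   bilinear projection t(U) \%*\% W \%*\% V.
#' @export
predict.tsa_projection <- function(object, mats, ...) {
  out <- t(vapply(mats, function(W)
    as.numeric(t(object$U) %*% W %*% object$V),
    numeric(object$d1 * object$d2)))
  colnames(out) <- paste0("tsa", seq_len(ncol(out)))
  out
}

#' Tensor-subspace feature matrix
#'
#' Convenience wrapper fitting [tsa_fit()] on all supplied graphs and
#' returning the projected feature matrix (d1 * d2 features per subject,
#' 36 by default).  For cross-validated classification use
#' [crossvalidate()], which refits the projection inside every training
#' fold.
#'
#' @inheritParams tsa_fit
#' @return Matrix, subjects x (d1 * d2).
#' @export
tsa_features <- function(mats, y, d1 = 6, d2 = 6, n_iter = 5) {
  fit <- tsa_fit(mats, y, d1 = d1, d2 = d2, n_iter = n_iter)
  predict(fit, mats)
}

#' Edge-weight feature matrix from per-subject graphs
#'
#' Vectorizes the upper triangle of each subject's single-layer graphs
#' into a subjects x features matrix: N(N-1)/2 features per layer, layers
#' concatenated in fixed order (so one layer gives N(N-1)/2 features, the
#' full 28-layer set gives 28 N(N-1)/2).
#'
#' @param subject_graphs List over subjects; each element a list of
#'   `sl_fcg` (or a single `sl_fcg`).
#' @return Numeric matrix with feature names `mode|roi_i|roi_j`.
#' @export
edge_feature_matrix <- function(subject_graphs) {
  rows <- lapply(subject_graphs, function(gs) {
    ed <- fcg_edges(gs)
    stats::setNames(ed$weight, paste(ed$mode, ed$roi_i, ed$roi_j, sep = "|"))
  })
  nm <- names(rows[[1]])
  stopifnot(all(vapply(rows, function(r) identical(names(r), nm),
                       logical(1))))
  X <- do.call(rbind, rows)
  rownames(X) <- names(subject_graphs)
  X
}
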
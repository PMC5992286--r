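#' Classification metrics from confusion counts
#'
#' Sensitivity = TP / (TP + FN), specificity = TN / (TN + FP), accuracy =
#' (TP + TN) / total, with the patient group as the positive class.  An
#' empty class yields `NA` for the affected metric (flagged, never a
#' silent 0).
#'
#' @param tp,fn,tn,fp Non-negative confusion counts.
#' @return One-row tibble with `sensitivity`, `specificity`, `accuracy`.
#' @export
metrics <- function(tp, fn, tn, fp) {
  tp <- unname(tp); fn <- unname(fn); tn <- unname(tn); fp <- unname(fp)
  stopifnot(tp >= 0, fn >= 0, tn >= 0, fp >= 0, tp + fn + tn + fp > 0)
  sens <- if (tp + fn == 0) NA_real_ else tp / (tp + fn)
  spec <- if (tn + fp == 0) NA_real_ else tn / (tn + fp)
  if (is.na(sens) || is.na(spec))
    warning("empty class: undefined metric reported as NA")
  tibble::tibble(sensitivity = sens, specificity = spec,
                 accuracy = (tp + tn) / (tp + fn + tn + fp))
}

# stratified k-fold assignment, deterministic given seed
stratified_folds <- function(y, k, seed) {
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in levels(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  fold
}

zscore_fit <- function(X) {
  mu <- colMeans(X)
  sd <- apply(X, 2, stats::sd)
  sd[sd == 0] <- 1
  list(mu = mu, sd = sd)
}

zscore_apply <- function(X, sc) sweep(sweep(X, 2, sc$mu), 2, sc$sd, "/")

fit_svm <- function(X, y, cost, gamma) {
  if (is.null(gamma)) gamma <- 1 / (ncol(X) * mean(apply(X, 2, stats::var)))
  if (!is.finite(gamma) || gamma <= 0) gamma <- 1 / ncol(X)
  e1071::svm(X, y, kernel = "radial", cost = cost, gamma = gamma,
             scale = FALSE)
}

#' Cross-validated connectome classification
#'
#' Classifies subjects from connectivity-derived features with an SVM
#' (RBF kernel) under leave-one-out or stratified k-fold
#' cross-validation.  Every data-dependent step -- z-scoring,
#' mutual-information feature ranking (edge route) and the TSA projection
#' (tensor route) -- is fitted inside each training fold only, so the
#' held-out subjects never influence feature selection.
#'
#' Routes: `"edge"` ranks single edge weights by mRMR mutual information
#' and keeps the top `k_rank` per fold, reporting the `m_consensus` most
#' frequently selected features across folds; `"tensor"` fits a TSA
#' projection per fold and classifies the d1 x d2 projected features;
#' `"mpc"` (or any precomputed feature set) uses the supplied columns
#' as-is.
#'
#' @param features_source Subjects x features numeric matrix (edge / mpc
#'   routes) or a list of per-subject square matrices (tensor route).
#' @param y Two-level factor of group labels; the second level is treated
#'   as the positive (patient) class.
#' @param scheme `"loocv"` or `"kfold"`.
#' @param route `"edge"`, `"tensor"` or `"mpc"`.
#' @param k_rank Features ranked per fold on the edge route (default 15).
#' @param m_consensus Consensus features reported (default 15).
#' @param d1,d2 TSA projection dimensions (default 6, giving 36 features).
#' @param k_folds Folds for the k-fold scheme (default 5, stratified).
#' @param seed Seed for the fold assignment (default 1).
#' @param cost,gamma SVM hyperparameters; `gamma = NULL` uses
#'   1 / (n_features * mean feature variance).
#' @return A `cv_result`; see [glance.cv_result()] and [tidy.cv_result()].
#' @export
crossvalidate <- function(features_source, y,
                          scheme = c("loocv", "kfold"),
                          route = c("edge", "tensor", "mpc"),
                          k_rank = 15, m_consensus = 15, d1 = 6, d2 = 6,
                          k_folds = 5, seed = 1, cost = 1, gamma = NULL) {
  scheme <- match.arg(scheme)
  route <- match.arg(route)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("need exactly two classes")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  n <- length(y)
  if (route == "tensor") {
    stopifnot(is.list(features_source), length(features_source) == n)
  } else {
    features_source <- as.matrix(features_source)
    stopifnot(nrow(features_source) == n)
    nm <- colnames(features_source)
    if (is.null(nm)) nm <- rep("", ncol(features_source))
    blank <- !nzchar(nm)
    nm[blank] <- paste0("f", which(blank))
    colnames(features_source) <- nm
  }

  fold <- if (scheme == "loocv") seq_len(n)
          else stratified_folds(y, k_folds, seed)
  n_fold <- max(fold)
  for (f in seq_len(n_fold))
    if (nlevels(droplevels(y[fold != f])) < 2)
      stop("a class is absent from the training split of fold ", f,
           "; resample folds")

  pred <- factor(rep(NA, n), levels = levels(y))
  rankings <- list()
  for (f in seq_len(n_fold)) {
    tr <- which(fold != f); te <- which(fold == f)
    if (route == "tensor") {
      proj <- tsa_fit(features_source[tr], y[tr], d1 = d1, d2 = d2)
      Xtr <- predict(proj, features_source[tr])
      Xte <- predict(proj, features_source[te])
      sc <- zscore_fit(Xtr)
      Xtr <- zscore_apply(Xtr, sc); Xte <- zscore_apply(Xte, sc)
    } else {
      sc <- zscore_fit(features_source[tr, , drop = FALSE])
      Xtr <- zscore_apply(features_source[tr, , drop = FALSE], sc)
      Xte <- zscore_apply(features_source[te, , drop = FALSE], sc)
      if (route == "edge") {
        sel <- rank_features_mi(Xtr, y[tr], k = k_rank)
        nm <- colnames(Xtr)
        rankings[[f]] <- if (is.null(nm)) sel else nm[sel]
        Xtr <- Xtr[, sel, drop = FALSE]
        Xte <- Xte[, sel, drop = FALSE]
      }
    }
    fit <- fit_svm(Xtr, y[tr], cost = cost, gamma = gamma)
    pred[te] <- stats::predict(fit, Xte)
  }

  pos <- levels(y)[2]; neg <- levels(y)[1]
  conf <- function(idx) {
    c(tp = sum(pred[idx] == pos & y[idx] == pos),
      fn = sum(pred[idx] == neg & y[idx] == pos),
      tn = sum(pred[idx] == neg & y[idx] == neg),
      fp = sum(pred[idx] == pos & y[idx] == neg))
  }
  if (scheme == "loocv") {
    cm <- conf(seq_len(n))
    overall <- metrics(cm["tp"], cm["fn"], cm["tn"], cm["fp"])
    per_fold <- NULL
    sds <- tibble::tibble(sensitivity = NA_real_, specificity = NA_real_,
                          accuracy = NA_real_)
  } else {
    per_fold <- purrr::map_dfr(seq_len(n_fold), function(f) {
      cm <- conf(which(fold == f))
      dplyr::mutate(metrics(cm["tp"], cm["fn"], cm["tn"], cm["fp"]),
                    fold = f, .before = 1)
    })
    overall <- tibble::tibble(
      sensitivity = mean(per_fold$sensitivity),
      specificity = mean(per_fold$specificity),
      accuracy = mean(per_fold$accuracy))
    sds <- tibble::tibble(
      sensitivity = stats::sd(per_fold$sensitivity),
      specificity = stats::sd(per_fold$specificity),
      accuracy = stats::sd(per_fold$accuracy))
    cm <- conf(seq_len(n))
  }
  consensus <- if (route == "edge")
    consensus_features(rankings, m = m_consensus) else NULL
  structure(list(scheme = scheme, route = route, metrics = overall,
                 metrics_sd = sds, confusion = cm, per_fold = per_fold,
                 predictions = tibble::tibble(subject = seq_len(n),
                                              truth = y, pred = pred,
                                              fold = fold),
                 consensus_features = consensus,
                 fold_rankings = if (route == "edge") rankings else NULL),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("<cv_result> %s / %s route\n", x$scheme, x$route))
  cat(sprintf("  accuracy %.3f, sensitivity %.3f, specificity %.3f\n",
              x$metrics$accuracy, x$metrics$sensitivity,
              x$metrics$specificity))
  invisible(x)
}
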
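test_that("confusion metrics follow their definitions", {
  expect_equal(metrics(10, 0, 10, 0),
               tibble::tibble(sensitivity = 1, specificity = 1,
                              accuracy = 1))
  expect_equal(metrics(0, 10, 10, 0)$sensitivity, 0)
  expect_equal(metrics(0, 10, 10, 0)$accuracy, 0.5)
  m <- metrics(7, 3, 6, 4)
  expect_equal(unlist(m), c(sensitivity = 0.7, specificity = 0.6,
                            accuracy = 0.65))
  expect_warning(m <- metrics(0, 0, 5, 5), "empty class")
  expect_true(is.na(m$sensitivity))
})

test_that("MI ranking puts a label-copy first and penalizes redundancy", {
  set.seed(71)
  y <- factor(rep(1:2, each = 20))
  X <- cbind(as.numeric(y) + rnorm(40, sd = 1e-6),   # = y
             rnorm(40), rnorm(40))
  expect_equal(rank_features_mi(X, y, k = 1), 1L)
  # duplicate of the top feature must not be ranked second when an
  # informative non-redundant feature exists: the duplicate's redundancy
  # (its full entropy) exceeds its relevance, the independent feature's
  # redundancy with the top pick is near zero
  top <- as.numeric(y) + rnorm(40, sd = 0.3)
  info <- as.numeric(y) + rnorm(40, sd = 0.6)
  X <- cbind(top, top, info)
  r <- rank_features_mi(X, y, k = 3)
  expect_true(r[1] %in% 1:2)
  expect_equal(unname(r[2]), 3L)
  # constant features never error and carry zero relevance
  X <- cbind(rep(1, 40), as.numeric(y))
  expect_equal(rank_features_mi(X, y, k = 1), 2L)
})

test_that("MI ranking on pure noise shows no preferred feature", {
  set.seed(72)
  y <- factor(rep(1:2, each = 15))
  top1 <- replicate(100, {
    X <- matrix(rnorm(30 * 8), 30)
    rank_features_mi(X, y, k = 1)
  })
  counts <- tabulate(top1, 8)
  # goodness of fit against the uniform distribution over features
  expect_gt(chisq.test(counts, p = rep(1 / 8, 8))$p.value, 0.001)
})

test_that("consensus features follow frequency then mean-rank tie-breaks", {
  r <- list(c(3, 1, 2), c(3, 1, 2), c(3, 1, 2))
  cf <- consensus_features(r, 2)
  expect_equal(cf$feature, c(3, 1))
  # one fold disagrees: majority feature kept
  r <- list(c(1, 2), c(1, 2), c(1, 3))
  expect_true(2 %in% consensus_features(r, 2)$feature)
  # frequency table {a:5, b:5, c:4} -> {a, b}; a before b via mean rank
  r <- c(rep(list(c("a", "b")), 4), list(c("b", "a", "c")),
         rep(list("c"), 3))
  cf <- consensus_features(r, 2)
  expect_setequal(cf$feature, c("a", "b"))
  expect_equal(cf$feature[1], "a")
  expect_warning(consensus_features(list(1:2), 5), "distinct")
})

test_that("TSA yields d1*d2 features and separates a planted block difference", {
  set.seed(73)
  mats <- lapply(1:20, function(s) {
    W <- matrix(rnorm(100), 10); W <- (W + t(W)) / 2; diag(W) <- 0
    if (s > 10) W[1:3, 1:3] <- W[1:3, 1:3] + 2
    W
  })
  y <- rep(1:2, each = 10)
  F <- tsa_features(mats, y)
  expect_equal(dim(F), c(20, 36))
  sv <- e1071::svm(F, factor(y), kernel = "linear")
  expect_equal(mean(predict(sv, F) == factor(y)), 1)
  expect_error(tsa_fit(mats, y, d1 = 11), "exceed")
})

test_that("full-rank TSA projection is an exact rotation", {
  set.seed(74)
  mats <- lapply(1:8, function(s) matrix(rnorm(36), 6))
  p <- tsa_fit(mats, rep(1:2, each = 4), d1 = 6, d2 = 6)
  W <- mats[[3]]
  expect_lt(max(abs(p$U %*% (t(p$U) %*% W %*% p$V) %*% t(p$V) - W)), 1e-8)
})

test_that("edge feature counts follow N(N-1)/2 per layer", {
  plan <- small_cohort_plan(n_rois = 5, seed = 12)
  co <- generate_cohort(plan, 2, epochs = 2, epoch_len_s = 2)
  md <- coupling_modes()
  graphs <- lapply(co$recordings, function(r)
    build_sl_fcgs(r, "iPLV", modes = md[md$kind == "intra", ]))
  X <- edge_feature_matrix(graphs)
  expect_equal(ncol(X), 7 * 5 * 4 / 2)
  expect_equal(nrow(X), 4)
  # single-layer route
  g1 <- lapply(co$recordings, function(r)
    build_sl_fcgs(r, "iPLV", modes = md[3, ]))
  expect_equal(ncol(edge_feature_matrix(g1)), 10)
})

test_that("a perfectly separating feature gives LOOCV accuracy 1", {
  set.seed(75)
  y <- factor(rep(1:2, each = 10))
  X <- cbind(sep = as.numeric(y) + rnorm(20, sd = 0.05),
             matrix(rnorm(20 * 5), 20))
  cv <- crossvalidate(X, y, scheme = "loocv", route = "edge", k_rank = 1,
                      m_consensus = 1)
  expect_equal(cv$metrics$accuracy, 1)
  expect_equal(cv$metrics$sensitivity, 1)
  expect_equal(cv$metrics$specificity, 1)
  # LOOCV accuracy equals pooled-confusion accuracy exactly
  cm <- cv$confusion
  expect_equal(cv$metrics$accuracy,
               (cm["tp"] + cm["tn"]) / sum(cm), ignore_attr = TRUE)
  # the separating feature dominates the consensus list
  expect_equal(cv$consensus_features$feature[1], "sep")
})

test_that("fold artifacts are leakage-free: held-out labels never matter", {
  set.seed(76)
  y <- factor(rep(1:2, each = 8))
  X <- matrix(rnorm(16 * 12), 16)
  colnames(X) <- paste0("f", 1:12)
  run_fold <- function(y_use) {
    tr <- 2:16   # subject 1 held out
    sc <- mlfcg:::zscore_fit(X[tr, ])
    Xtr <- mlfcg:::zscore_apply(X[tr, ], sc)
    rank_features_mi(Xtr, y_use[tr], k = 5)
  }
  y_corrupt <- y
  y_corrupt[1] <- factor(2, levels = levels(y))
  expect_identical(run_fold(y), run_fold(y_corrupt))
  # the fold holding subject 1 out must select the same features and
  # predict the same label whatever subject 1's label claims to be
  cv1 <- crossvalidate(X, y, scheme = "loocv", route = "edge", k_rank = 5,
                       m_consensus = 5)
  cv2 <- crossvalidate(X, y_corrupt, scheme = "loocv", route = "edge",
                       k_rank = 5, m_consensus = 5)
  expect_identical(cv1$predictions$pred[1], cv2$predictions$pred[1])
  expect_identical(cv1$fold_rankings[[1]], cv2$fold_rankings[[1]])
})

test_that("stratified folds keep both classes in every training split", {
  y <- factor(c(rep(1, 11), rep(2, 9)))
  f <- mlfcg:::stratified_folds(y, 5, seed = 3)
  expect_equal(sort(unique(f)), 1:5)
  for (k in 1:5)
    expect_equal(nlevels(droplevels(y[f != k])), 2)
  expect_identical(f, mlfcg:::stratified_folds(y, 5, seed = 3))
})

test_that("crossvalidate validates inputs", {
  y <- factor(rep(1:2, each = 5))
  X <- matrix(rnorm(30), 10)
  expect_error(crossvalidate(X, factor(rep(1, 10))), "two classes")
  expect_error(crossvalidate(X[1:3, ], factor(c(1, 1, 2))), "at least 2")
})
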
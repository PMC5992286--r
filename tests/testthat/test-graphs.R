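test_that("global efficiency matches hand-computed values", {
  expect_equal(global_efficiency(matrix(1, 4, 4) - diag(4)), 1)
  expect_equal(global_efficiency(matrix(0, 2, 2)), 0)
  # 4-node path with unit weights: pair distances {1,1,1,2,2,3}
  W <- matrix(0, 4, 4)
  W[1, 2] <- W[2, 3] <- W[3, 4] <- 1
  W <- W + t(W)
  expect_equal(global_efficiency(W), 13 / 18)
  expect_error(global_efficiency(matrix(1, 3, 3)), "diagonal")
})

test_that("global efficiency agrees with an independent Floyd-Warshall oracle", {
  set.seed(61)
  for (i in 1:20) {
    W <- random_weighted_graph(6)
    W[W < 0.4] <- 0    # some sparsity, possibly disconnected pairs
    diag(W) <- 0
    expect_equal(global_efficiency(W), fw_global_efficiency(W),
                 tolerance = 1e-12)
  }
})

test_that("OMST round 1 is the classical MST and rounds are edge-disjoint", {
  set.seed(62)
  W <- random_weighted_graph(8)
  om <- omst_filter(W)
  r1 <- om$selected_edges[[1]]
  expect_equal(nrow(r1), 7)                         # spanning tree size
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  mt <- igraph::mst(g, weights = 1 / igraph::E(g)$weight)
  expect_equal(sum(r1$w), sum(W[igraph::as_edgelist(mt)]))
  keys <- unlist(lapply(om$selected_edges, function(e)
    paste(e$i, e$j)))
  expect_equal(anyDuplicated(keys), 0)
})

test_that("OMST peak matches brute-force search over accumulated rounds", {
  set.seed(63)
  for (i in 1:30) {
    W <- random_weighted_graph(5)
    om <- omst_filter(W)
    J_bf <- vapply(seq_along(om$selected_edges), function(k) {
      sel <- do.call(rbind, om$selected_edges[1:k])
      A <- matrix(0, 5, 5)
      A[cbind(sel$i, sel$j)] <- sel$w
      A <- A + t(A)
      fw_global_efficiency(A) - sum(A) / 2 / (sum(W) / 2)
    }, numeric(1))
    expect_equal(om$peak_round, which.max(J_bf))
    expect_equal(om$J_curve$J, J_bf, tolerance = 1e-12)
  }
})

test_that("OMST invariants: GE non-decreasing, cost increasing, J = GE - cost", {
  set.seed(64)
  W <- random_weighted_graph(10)
  om <- omst_filter(W)
  cv <- om$J_curve
  expect_true(all(diff(cv$ge) >= -1e-12))
  expect_true(all(diff(cv$cost) > 0))
  expect_equal(cv$J, cv$ge - cv$cost)
  expect_error(omst_filter(diag(0, 4) + rbind(cbind(matrix(1, 2, 2), 0, 0),
                                              matrix(0, 2, 4)) -
                             diag(c(1, 1, 0, 0))), "disconnected")
})

test_that("OMST of a bare tree keeps the tree with cost 1", {
  W <- matrix(0, 5, 5)
  for (k in 1:4) { W[k, k + 1] <- k; W[k + 1, k] <- k }
  om <- omst_filter(W)
  expect_equal(nrow(om$J_curve), 1)
  expect_equal(om$J_curve$cost, 1)
  expect_equal(om$W_filtered, W, ignore_attr = TRUE)
})

test_that("multilayer assembly flattens 28 layers into band blocks", {
  plan <- small_cohort_plan(n_rois = 4, seed = 8)
  co <- generate_cohort(plan, 2, epochs = 2, epoch_len_s = 2)
  gs <- build_sl_fcgs(co$recordings[[1]], "iPLV")
  ml <- assemble_mlfcg(gs)
  expect_equal(nrow(ml$flattened), 7 * 4)
  expect_true(isSymmetric(ml$flattened))
  # diagonal block = intra layer, off-diagonal block = cross layer
  expect_equal(ml$flattened[1:4, 1:4], unname(gs$delta$W))
  blk <- function(a) ((a - 1) * 4 + 1):(a * 4)
  expect_equal(ml$flattened[blk(1), blk(7)],
               unname(gs$`delta:gamma1`$W))
  expect_error(assemble_mlfcg(gs[1:27]), "28")
  expect_error(assemble_mlfcg(rev(gs)), "order")
})

test_that("MPC analytic limits hold and invariances are respected", {
  n <- 6
  # all connections in one layer -> 0
  layers <- c(list(star_layer(n, 5)), rep(list(star_layer(n, 0)), 27))
  m <- mpc(layers)
  expect_equal(m$per_node$mpc[1], 0)
  # equal degree in every layer -> 1
  layers <- rep(list(star_layer(n, 3)), 28)
  m <- suppressWarnings(mpc(layers))
  expect_equal(m$per_node$mpc[1], 1)
  # M = 2, degrees (3, 1): 2 * (1 - 0.625) = 0.75
  m <- mpc(list(star_layer(n, 3), star_layer(n, 1)))
  expect_equal(m$per_node$mpc[1], 0.75)
  # isolated node -> 0, global is the mean
  expect_equal(m$per_node$mpc[6], 0)
  expect_equal(m$global, mean(m$per_node$mpc))
  # layer order permutation and weight scaling leave binary MPC unchanged
  set.seed(65)
  layers <- lapply(1:5, function(i) {
    W <- random_weighted_graph(n); W[W < 0.5] <- 0; W
  })
  m1 <- suppressWarnings(mpc(layers))
  m2 <- suppressWarnings(mpc(rev(layers)))
  m3 <- suppressWarnings(mpc(lapply(layers, function(W) 3.7 * W)))
  expect_equal(m1$per_node$mpc, m2$per_node$mpc)
  expect_equal(m1$per_node$mpc, m3$per_node$mpc)
})

test_that("dense layers trigger the filtering warning", {
  expect_warning(mpc(rep(list(matrix(1, 4, 4) - diag(4)), 3)), "dense")
})

test_that("comodulogram cells are a probability distribution over 28 layers", {
  plan <- small_cohort_plan(n_rois = 4, seed = 10)
  co <- generate_cohort(plan, 2, epochs = 2, epoch_len_s = 2)
  gs <- build_sl_fcgs(co$recordings[[1]], "iPLV")
  ml <- assemble_mlfcg(gs)
  cm <- comodulogram(omst_filter(ml$flattened), n_rois = 4)
  expect_equal(nrow(cm$table), 28)
  expect_equal(sum(cm$table$pd), 1, tolerance = 1e-12)
  expect_true(all(cm$table$pd >= 0))
})

test_that("retained edges in a single block put all comodulogram mass there", {
  # a filtered multilayer whose retained edges all sit inside the delta
  # block: PD(delta, delta) = 1, all other cells 0
  N <- 3; side <- 7 * N
  Wf <- matrix(0, side, side)
  Wf[1, 2] <- Wf[2, 3] <- Wf[1, 3] <- 1
  Wf <- Wf + t(Wf)
  om <- structure(list(W_filtered = Wf), class = "omst_result")
  cm <- comodulogram(om, n_rois = N)
  expect_equal(cm$table$pd[cm$table$mode == "delta"], 1)
  expect_equal(sum(cm$table$pd), 1)
  # empty selection is an error
  om0 <- structure(list(W_filtered = matrix(0, side, side)),
                   class = "omst_result")
  expect_error(comodulogram(om0, n_rois = N), "no edges")
})
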
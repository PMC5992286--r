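check_weight_matrix <- function(W) {
  stopifnot(is.matrix(W), nrow(W) == ncol(W))
  if (!isSymmetric(unname(W))) stop("weight matrix must be symmetric")
  if (any(W < 0) || any(!is.finite(W))) stop("weights must be finite and >= 0")
  if (any(diag(W) != 0)) stop("diagonal must be zero")
  invisible(W)
}

#' Weighted global efficiency
#'
#' GE = mean over ordered node pairs of 1/d(i, j), where d is the weighted
#' shortest-path length on edge distances 1/w (stronger edges are
#' shorter).  Unreachable pairs contribute 0; the empty graph has GE 0.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @return Scalar in \[0, max weight\]; 1 for the complete unit-weight
#'   graph.
#' @export
global_efficiency <- function(W) {
  check_weight_matrix(W)
  n <- nrow(W)
  if (n < 2 || all(W == 0)) return(0)
  g <- igraph::graph_from_adjacency_matrix(W, mode = "undirected",
                                           weighted = TRUE)
  d <- igraph::distances(g, weights = 1 / igraph::E(g)$weight)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (n * (n - 1))
}

# Kruskal MST on distances 1/w with a deterministic tie-break:
# (smaller distance, then smaller node index pair).  Returns an edge-index
# logical over the rows of `edges` (cols i, j, w).
kruskal_mst <- function(n, edges) {
  ord <- order(1 / edges$w, edges$i, edges$j)
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  keep <- logical(nrow(edges))
  taken <- 0L
  for (k in ord) {
    ra <- find(edges$i[k]); rb <- find(edges$j[k])
    if (ra != rb) {
      parent[ra] <- rb
      keep[k] <- TRUE
      taken <- taken + 1L
      if (taken == n - 1L) break
    }
  }
  if (taken < n - 1L) NULL else keep
}

#' Orthogonal minimal spanning trees (OMST) topological filtering
#'
#' Extracts successive minimal spanning trees that are edge-disjoint
#' ("orthogonal"): round r takes the MST (on distances 1/w) of the graph
#' restricted to edges not selected in earlier rounds.  After each round
#' the aggregate filtered graph is scored by J = GE - Cost, with GE the
#' weighted global efficiency of the aggregate and Cost the ratio of
#' selected weight to the total weight of the input graph.  Extraction
#' stops when the remaining graph no longer spans all nodes or when J has
#' declined for `patience` consecutive rounds; the returned filtered graph
#' is the aggregate at the (first) maximum of J.
#'
#' @param W Symmetric non-negative weight matrix, connected on its
#'   positive edges.
#' @param patience Consecutive declining rounds tolerated before stopping
#'   (default 5).
#' @param max_rounds Optional hard cap on rounds.
#' @return An `omst_result`: list with `selected_edges` (per-round tibbles
#'   of i, j, w), `J_curve` (tibble round, ge, cost, J), `peak_round`, and
#'   `W_filtered` (matrix keeping the original weights of edges selected
#'   up to the peak round).
#' @export
omst_filter <- function(W, patience = 5, max_rounds = Inf) {
  check_weight_matrix(W)
  n <- nrow(W)
  g0 <- igraph::graph_from_adjacency_matrix((W > 0) * 1, mode = "undirected")
  comp <- igraph::components(g0)
  if (comp$no > 1)
    stop("input graph is disconnected (", comp$no, " components)")
  ut <- which(upper.tri(W) & W > 0, arr.ind = TRUE)
  edges <- tibble::tibble(i = ut[, 1], j = ut[, 2], w = W[ut])
  total_w <- sum(edges$w)

  available <- rep(TRUE, nrow(edges))
  sel_mask <- matrix(FALSE, n, n)
  rounds <- list(); curve <- list()
  best_J <- -Inf; declines <- 0L; r <- 0L
  repeat {
    r <- r + 1L
    keep <- kruskal_mst(n, edges[available, , drop = FALSE])
    if (is.null(keep)) { r <- r - 1L; break }    # remaining graph disconnected
    sel <- which(available)[keep]
    available[sel] <- FALSE
    rounds[[r]] <- edges[sel, ]
    sel_mask[cbind(edges$i[sel], edges$j[sel])] <- TRUE
    sel_mask[cbind(edges$j[sel], edges$i[sel])] <- TRUE
    Wagg <- W * sel_mask
    ge <- global_efficiency(Wagg)
    cost <- sum(Wagg) / 2 / total_w
    J <- ge - cost
    prev_J <- if (r > 1) curve[[r - 1]]$J else -Inf
    curve[[r]] <- tibble::tibble(round = r, ge = ge, cost = cost, J = J)
    declines <- if (J < prev_J) declines + 1L else 0L
    if (declines >= patience || r >= max_rounds || !any(available)) break
  }
  if (r == 0L) stop("no spanning tree could be extracted")
  curve <- dplyr::bind_rows(curve)
  peak <- which.max(curve$J)
  Wf <- matrix(0, n, n)
  for (k in seq_len(peak)) {
    Wf[cbind(rounds[[k]]$i, rounds[[k]]$j)] <- rounds[[k]]$w
    Wf[cbind(rounds[[k]]$j, rounds[[k]]$i)] <- rounds[[k]]$w
  }
  dimnames(Wf) <- dimnames(W)
  structure(list(selected_edges = rounds, J_curve = curve,
                 peak_round = peak, W_filtered = Wf),
            class = "omst_result")
}

#' @export
print.omst_result <- function(x, ...) {
  cat(sprintf(
    "<omst_result> %d rounds, peak at round %d (J = %.4f): %d edges kept\n",
    nrow(x$J_curve), x$peak_round, max(x$J_curve$J),
    sum(x$W_filtered[upper.tri(x$W_filtered)] > 0)))
  invisible(x)
}

#' Assemble the multilayer graph and its flattened view
#'
#' Stacks the full set of single-layer graphs (B intra + choose(B, 2)
#' cross, in fixed layer order) into a multilayer graph and builds the
#' flattened (B*N) x (B*N) supra-adjacency view: intra-band graphs on the
#' diagonal blocks, the cross-frequency graph of band pair (a, b) in
#' off-diagonal block (a, b), mirrored in (b, a).  With 7 bands and 90
#' ROIs the flattened side is 630.
#'
#' @param slfcgs List of `sl_fcg` in the order of [coupling_modes()].
#' @param bands Band table the layers were built from.
#' @return An `ml_fcg`: list with `layers`, `flattened`, `n_rois`,
#'   `modes`.
#' @export
assemble_mlfcg <- function(slfcgs, bands = default_bands()) {
  modes <- coupling_modes(bands)
  if (length(slfcgs) != nrow(modes))
    stop("expected ", nrow(modes), " layers, got ", length(slfcgs))
  got <- vapply(slfcgs, function(g) g$mode, character(1))
  if (!identical(unname(got), modes$mode))
    stop("layer order mismatch: expected fixed intra-then-cross band order")
  N <- nrow(slfcgs[[1]]$W)
  stopifnot(all(vapply(slfcgs, function(g) nrow(g$W), integer(1)) == N))
  B <- nrow(bands)
  side <- B * N
  flat <- matrix(0, side, side)
  blk <- function(a) ((a - 1) * N + 1):(a * N)
  bidx <- function(nm) match(nm, as.character(bands$band))
  for (m in seq_len(nrow(modes))) {
    a <- bidx(modes$band_a[m]); b <- bidx(modes$band_b[m])
    flat[blk(a), blk(b)] <- slfcgs[[m]]$W
    if (a != b) flat[blk(b), blk(a)] <- t(slfcgs[[m]]$W)
  }
  structure(list(layers = slfcgs, flattened = flat, n_rois = N,
                 modes = modes),
            class = "ml_fcg")
}

#' @export
print.ml_fcg <- function(x, ...) {
  cat(sprintf("<ml_fcg> %d layers, %d ROIs, flattened side %d\n",
              length(x$layers), x$n_rois, nrow(x$flattened)))
  invisible(x)
}

#' Multilayer participation coefficient
#'
#' Quantifies how evenly each node's connections spread across the M
#' layers of a multilayer graph.  With binary layer degrees k_i\[l\], layer
#' proportions NLP_i\[l\] = k_i\[l\] / o_i (o_i the total degree across
#' layers), MPC_i = M / (M - 1) * (1 - sum_l NLP_i\[l\]^2): 0 when all of
#' a node's connections sit in one layer, 1 when they spread evenly over
#' all layers.  Nodes with no connections get MPC_i = 0.  Intended for
#' OMST-filtered layers; dense layers are accepted with a warning.
#'
#' @param layers List of `sl_fcg` objects or weight matrices (the layers),
#'   or an `ml_fcg`.
#' @param weighted If `TRUE` use layer strengths (sum of weights) instead
#'   of binary degrees.
#' @return An `mpc_result`: list with `per_node` tibble (roi, mpc) and
#'   `global` (mean of per-node values).
#' @export
mpc <- function(layers, weighted = FALSE) {
  if (inherits(layers, "ml_fcg")) layers <- layers$layers
  mats <- lapply(layers, function(l) if (inherits(l, "sl_fcg")) l$W else l)
  lapply(mats, check_weight_matrix)
  M <- length(mats)
  stopifnot(M >= 2)
  N <- nrow(mats[[1]])
  dens <- mean(vapply(mats, function(W)
    mean(W[upper.tri(W)] > 0), numeric(1)))
  if (dens > 0.9)
    warning("layers look dense; MPC is intended for topologically ",
            "filtered layers")
  K <- vapply(mats, function(W) {
    if (weighted) colSums(W) else colSums(W > 0)
  }, numeric(N))                                # N x M
  o <- rowSums(K)
  nlp2 <- rowSums((K / ifelse(o == 0, 1, o))^2)
  val <- M / (M - 1) * (1 - nlp2)
  val[o == 0] <- 0
  labels <- rownames(mats[[1]])
  if (is.null(labels)) labels <- sprintf("ROI%02d", seq_len(N))
  structure(list(per_node = tibble::tibble(roi = labels, mpc = val),
                 global = mean(val)),
            class = "mpc_result")
}

#' @export
print.mpc_result <- function(x, ...) {
  cat(sprintf("<mpc_result> %d nodes, global MPC = %.3f\n",
              nrow(x$per_node), x$global))
  invisible(x)
}

flat_edge_layers <- function(W_flat, n_rois, modes, bands) {
  ut <- which(upper.tri(W_flat) & W_flat > 0, arr.ind = TRUE)
  a <- (ut[, 1] - 1) %/% n_rois + 1
  b <- (ut[, 2] - 1) %/% n_rois + 1
  lo <- pmin(a, b); hi <- pmax(a, b)
  nm <- as.character(bands$band)
  lab <- ifelse(lo == hi, nm[lo], paste0(nm[lo], ":", nm[hi]))
  match(lab, modes$mode)
}

#' Comodulogram of retained multilayer connections
#'
#' After OMST filtering of the flattened multilayer graph, tabulates the
#' fraction of retained connections that fall in each of the coupling-mode
#' layers (intra bands on the diagonal, cross-frequency pairs off it).
#' Cells sum to 1.
#'
#' @param omst An `omst_result` from running [omst_filter()] on the
#'   `flattened` matrix of an [assemble_mlfcg()] result.
#' @param n_rois Number of ROIs per band block.
#' @param bands Band table (default [default_bands()]).
#' @return A `comodulogram`: list with `table` (tibble band_a, band_b,
#'   kind, pd) and `n_edges`.
#' @export
comodulogram <- function(omst, n_rois, bands = default_bands()) {
  stopifnot(inherits(omst, "omst_result"))
  modes <- coupling_modes(bands)
  W <- omst$W_filtered
  if (nrow(W) != nrow(bands) * n_rois)
    stop("flattened side ", nrow(W), " does not match ",
         nrow(bands), " bands x ", n_rois, " ROIs")
  lay <- flat_edge_layers(W, n_rois, modes, bands)
  if (!length(lay)) stop("no edges selected by OMST; comodulogram undefined")
  counts <- tabulate(lay, nbins = nrow(modes))
  tab <- modes
  tab$pd <- counts / sum(counts)
  structure(list(table = tab[, c("mode", "kind", "band_a", "band_b", "pd")],
                 n_edges = sum(counts)),
            class = "comodulogram")
}

#' Average comodulograms across subjects
#'
#' @param comods List of `comodulogram` objects (one per subject).
#' @return A `comodulogram` whose cells are the arithmetic mean of the
#'   subjects' cells.
#' @export
average_comodulograms <- function(comods) {
  stopifnot(length(comods) >= 1,
            all(vapply(comods, inherits, logical(1), "comodulogram")))
  tab <- comods[[1]]$table
  tab$pd <- rowMeans(vapply(comods, function(cm) cm$table$pd,
                            numeric(nrow(tab))))
  structure(list(table = tab,
                 n_edges = mean(vapply(comods, function(cm) cm$n_edges,
                                       numeric(1)))),
            class = "comodulogram")
}

#' @export
print.comodulogram <- function(x, ...) {
  top <- x$table[which.max(x$table$pd), ]
  cat(sprintf(
    "<comodulogram> 28 cells summing to %.3f; dominant layer %s (pd = %.3f)\n",
    sum(x$table$pd), top$mode, top$pd))
  invisible(x)
}
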
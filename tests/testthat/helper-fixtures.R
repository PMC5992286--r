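# shared helpers for building tiny fixtures in code

FS <- 250

# downstream estimate on a generated pair: bandpass -> analytic -> trim ->
# estimator on phases or envelopes
pair_phase_stat <- function(pair, lo, hi, stat = plv, fs = FS) {
  px <- analytic(bandpass(pair$x, lo, hi, fs))$phase
  py <- analytic(bandpass(pair$y, lo, hi, fs))$phase
  stat(trim_edges(px, fs), trim_edges(py, fs))
}

pair_env_stat <- function(pair, lo, hi, fs = FS) {
  ex <- analytic(bandpass(pair$x, lo, hi, fs))$envelope
  ey <- analytic(bandpass(pair$y, lo, hi, fs))$envelope
  corr_env(trim_edges(ex, fs), trim_edges(ey, fs))
}

random_weighted_graph <- function(n, min_w = 0.05, max_w = 1) {
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- stats::runif(n * (n - 1) / 2, min_w, max_w)
  W + t(W)
}

# star layer on n nodes: node 1 connected to `deg` neighbours
star_layer <- function(n, deg) {
  W <- matrix(0, n, n)
  if (deg > 0) for (k in seq_len(deg)) {
    W[1, 1 + k] <- 1
    W[1 + k, 1] <- 1
  }
  W
}

# independent all-pairs shortest paths (Floyd-Warshall) for GE oracle
fw_global_efficiency <- function(W) {
  n <- nrow(W)
  D <- 1 / W
  D[W == 0] <- Inf
  diag(D) <- 0
  for (k in 1:n) for (a in 1:n) for (b in 1:n)
    if (D[a, k] + D[k, b] < D[a, b]) D[a, b] <- D[a, k] + D[k, b]
  I <- 1 / D
  I[!is.finite(I)] <- 0
  diag(I) <- 0
  sum(I) / (n * (n - 1))
}

small_cohort_plan <- function(edges = NULL, n_rois = 6, seed = 1)
  coupling_plan(n_rois = n_rois, edges = edges, seed = seed)
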
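test_that("all generators are bit-deterministic given a seed", {
  a <- generate_coupled_pair(c(8, 10), 1, 0.5, FS, 1000, seed = 9)
  b <- generate_coupled_pair(c(8, 10), 1, 0.5, FS, 1000, seed = 9)
  expect_identical(a, b)
  a <- generate_pac_pair(c(0.5, 4), c(30, 45), 0.7, 0, FS, 1000, seed = 9)
  b <- generate_pac_pair(c(0.5, 4), c(30, 45), 0.7, 0, FS, 1000, seed = 9)
  expect_identical(a, b)
  a <- generate_env_pair(c(8, 10), c(10, 13), 0.5, FS, 1000, seed = 9)
  b <- generate_env_pair(c(8, 10), c(10, 13), 0.5, FS, 1000, seed = 9)
  expect_identical(a, b)
  plan <- small_cohort_plan(seed = 7)
  c1 <- generate_cohort(plan, 2, epochs = 2, epoch_len_s = 1)
  c2 <- generate_cohort(plan, 2, epochs = 2, epoch_len_s = 1)
  expect_identical(c1, c2)
  v1 <- generate_roi_voxels(rnorm(100), 5, snr = 1, seed = 3)
  v2 <- generate_roi_voxels(rnorm(100), 5, snr = 1, seed = 3)
  expect_identical(v1[c("voxel_series", "voxel_coords")],
                   v2[c("voxel_series", "voxel_coords")])
})

test_that("fully locked pair reaches PLV 1 and zero-lag pair has zero iPLV", {
  for (s in 1:5) {
    p <- generate_coupled_pair(c(8, 10), pi / 2, 1, FS, 5000, seed = s)
    expect_equal(pair_phase_stat(p, 8, 10, plv), 1, tolerance = 1e-2)
    p0 <- generate_coupled_pair(c(8, 10), 0, 1, FS, 5000, seed = s)
    expect_equal(pair_phase_stat(p0, 8, 10, iplv), 0, tolerance = 1e-2)
  }
})

test_that("uncoupled pairs sit at the phase-locking noise floor", {
  # Monte-Carlo null at strength 0: mean downstream PLV below 0.05
  nulls <- vapply(1:20, function(s) {
    p <- generate_coupled_pair(c(8, 10), pi / 2, 0, FS, 60000, seed = s)
    pair_phase_stat(p, 8, 10, plv)
  }, numeric(1))
  expect_lt(mean(nulls), 0.05)
})

test_that("planted phase lag appears in the downstream circular mean", {
  p <- generate_coupled_pair(c(8, 10), pi / 3, 1, FS, 5000, seed = 2)
  px <- analytic(bandpass(p$x, 8, 10, FS))$phase
  py <- analytic(bandpass(p$y, 8, 10, FS))$phase
  dphi <- Arg(mean(exp(1i * (trim_edges(px, FS) - trim_edges(py, FS)))))
  expect_equal(dphi, pi / 3, tolerance = 0.05)
})

test_that("PAC pair modulates the HF envelope by the LF phase as planted", {
  p <- generate_pac_pair(c(0.5, 4), c(30, 45), 0.9, pi / 2, FS, 10000,
                         seed = 5)
  expect_gt(pac_iplv(p$x, p$y, c(0.5, 4), c(30, 45), FS), 0.8)
  # depth 0: PAC below its own 20-seed null 95th percentile
  null <- vapply(1:20, function(s) {
    q <- generate_pac_pair(c(0.5, 4), c(30, 45), 0, pi / 2, FS, 10000,
                           seed = 100 + s)
    pac_iplv(q$x, q$y, c(0.5, 4), c(30, 45), FS)
  }, numeric(1))
  m0 <- vapply(1:5, function(s) {
    q <- generate_pac_pair(c(0.5, 4), c(30, 45), 0, pi / 2, FS, 10000,
                           seed = s)
    pac_iplv(q$x, q$y, c(0.5, 4), c(30, 45), FS)
  }, numeric(1))
  expect_lt(mean(m0), quantile(null, 0.95))
  expect_error(generate_pac_pair(c(0.5, 8), c(4, 30), 0.5, 0, FS, 1000),
               "overlap")
})

test_that("PAC response is non-decreasing in modulation depth", {
  grid <- c(0, 0.3, 0.6, 0.9)
  resp <- vapply(grid, function(m) {
    mean(vapply(1:10, function(s) {
      p <- generate_pac_pair(c(0.5, 4), c(30, 45), m, pi / 2, FS, 5000,
                             seed = s)
      pac_iplv(p$x, p$y, c(0.5, 4), c(30, 45), FS)
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(resp) >= 0))
})

test_that("shared-envelope pairs track the planted mixing weight", {
  e1 <- vapply(1:5, function(s) {
    p <- generate_env_pair(c(8, 10), c(10, 13), 1, FS, 20000, seed = s)
    cfc_corr_env(p$x, p$y, c(8, 10), c(10, 13), FS)
  }, numeric(1))
  expect_true(all(e1 >= 0.9))
  e0 <- vapply(1:10, function(s) {
    p <- generate_env_pair(c(8, 10), c(10, 13), 0, FS, 60000, seed = s)
    cfc_corr_env(p$x, p$y, c(8, 10), c(10, 13), FS)
  }, numeric(1))
  expect_lt(mean(e0), 0.1)
  # identical series: envelope correlation is exactly 1
  x <- generate_env_pair(c(8, 10), c(8, 10), 1, FS, 5000, seed = 1)$x
  env <- analytic(bandpass(x, 8, 10, FS))$envelope
  expect_equal(corr_env(env, env), 1)
})

test_that("phase coupling does not leak into envelope correlation", {
  # cross-talk bound: locked pair's CorrEnv within its Monte-Carlo null
  null <- vapply(1:20, function(s) {
    p <- generate_coupled_pair(c(8, 10), pi / 2, 0, FS, 20000, seed = 200 + s)
    pair_env_stat(p, 8, 10)
  }, numeric(1))
  locked <- vapply(1:10, function(s) {
    p <- generate_coupled_pair(c(8, 10), pi / 2, 1, FS, 20000, seed = s)
    pair_env_stat(p, 8, 10)
  }, numeric(1))
  expect_lt(mean(locked), quantile(null, 0.95))
})

test_that("cohort generation validates its plan and realizes group effects", {
  expect_error(generate_cohort(small_cohort_plan(), 1), "at least 2")
  expect_error(coupling_plan(edges = tibble::tibble(
    roi_i = 1, roi_j = 1, kind = "intra", band_a = "delta",
    band_b = "delta", strength = 0.5, phase_lag = 0)))
  expect_error(coupling_plan(edges = tibble::tibble(
    roi_i = 1, roi_j = 2, kind = "pac", band_a = "gamma1",
    band_b = "delta", strength = 0.5, phase_lag = 0)))
  edges <- tibble::tibble(roi_i = 1, roi_j = 4, kind = "intra",
                          band_a = "alpha1", band_b = "alpha1",
                          strength = 0.2, phase_lag = pi / 2,
                          delta_strength = 0.5)
  co <- generate_cohort(small_cohort_plan(edges, seed = 5), 3,
                        epochs = 2, epoch_len_s = 2)
  expect_length(co$recordings, 6)
  expect_false(anyNA(co$truth$strength))
  s1 <- co$truth$strength[co$truth$group == 1]
  s2 <- co$truth$strength[co$truth$group == 2]
  expect_gt(mean(s2) - mean(s1), 0.3)   # delta_strength realized
  # subject jitter present but small
  expect_gt(sd(s1), 0)
  expect_lt(sd(s1), 0.15)
})

test_that("voxel clusters place voxel 1 at the centroid and honor snr", {
  src <- sin(2 * pi * 9 * (0:999) / FS)
  vc <- generate_roi_voxels(src, 10, snr = 1e9, seed = 2)
  expect_gte(abs(cor(roi_pca(vc), src)), 0.999)
  ctr <- colMeans(vc$voxel_coords)
  d <- sqrt(rowSums(sweep(vc$voxel_coords, 2, ctr)^2))
  expect_equal(which.min(d), 1)
  expect_error(generate_roi_voxels(src, 1, snr = 1), "2 voxels")
  expect_error(generate_roi_voxels(src, 5, snr = 0), "snr")
})

test_that("averaging across voxels (PCA) beats the single centroid voxel", {
  src <- mlfcg:::narrowband_oscillation(8, 10, FS, 1000)$x
  wins <- vapply(1:30, function(s) {
    vc <- generate_roi_voxels(src, 20, snr = 1, seed = s)
    abs(cor(roi_pca(vc), src)) > abs(cor(roi_centroid(vc), src))
  }, logical(1))
  expect_gt(mean(wins), 0.5)
})
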
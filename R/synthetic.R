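#' @importFrom rlang .data
NULL

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

as_band <- function(band) {
  if (is.data.frame(band)) {
    stopifnot(nrow(band) == 1)
    c(lo = band$lo, hi = band$hi)
  } else {
    stopifnot(is.numeric(band), length(band) == 2)
    c(lo = band[[1]], hi = band[[2]])
  }
}

#' Power-law (1/f) background noise
#'
#' Spectrally shaped white noise with power spectral density proportional
#' to 1/f^exponent, emulating the broadband resting-state floor of
#' electrophysiological recordings.
#'
#' @param n Number of samples.
#' @param fs Sampling rate (Hz).
#' @param exponent Spectral slope (power falls as 1/f^exponent); default 1.
#' @param seed Optional integer seed.
#' @return Numeric vector of length `n`, unit standard deviation.
#' @export
noise_1f <- function(n, fs, exponent = 1, seed = NULL) {
  with_seed(seed, {
    w <- stats::rnorm(n)
    f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
    f[f > fs / 2] <- fs - f[f > fs / 2]       # two-sided frequency axis
    g <- c(0, f[-1]^(-exponent / 2))          # kill DC
    x <- Re(stats::fft(g * stats::fft(w), inverse = TRUE)) / n
    as.numeric(x / stats::sd(x))
  })
}

narrowband_noise <- function(lo, hi, fs, n) {
  pad <- min(n, round(2 * fs))
  x <- bandpass(stats::rnorm(n + 2 * pad), lo, hi, fs)
  x <- x[(pad + 1):(pad + n)]
  x / stats::sd(x)
}

# band-limited Gaussian series (FFT mask, unit sd)
lowpass_gauss <- function(n, fs, f_max) {
  w <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(f > 0 & f <= f_max)
  z <- Re(stats::fft(g * stats::fft(w), inverse = TRUE)) / n
  z / stats::sd(z)
}

# stochastic narrowband oscillation with a smooth, slip-free phase:
# instantaneous frequency wanders inside the band (slow Gaussian
# deviation around the center frequency) and an independent slow positive
# envelope modulates the amplitude.  Unlike the phase of filtered noise,
# this phase has no slips at envelope minima, so planted phase lags
# survive re-filtering exactly.
narrowband_oscillation <- function(lo, hi, fs, n) {
  fc <- (lo + hi) / 2
  bw <- hi - lo
  floor_f <- 2 / (n / fs)
  # FM deviation sd bw/8 wandering at rate bw/3; AM at the slower bw/6:
  # slow enough that planted phase lags survive re-filtering, fast enough
  # that independent realizations decorrelate
  dev <- lowpass_gauss(n, fs, f_max = max(bw / 3, floor_f)) * bw / 8
  phase <- 2 * pi * cumsum(fc + dev) / fs
  env <- slow_envelope(n, fs, f_max = max(bw / 6, floor_f))
  list(phase = phase, envelope = env, x = env * cos(phase))
}

slow_envelope <- function(n, fs, f_max = 1) {
  w <- stats::rnorm(n)
  f <- seq(0, fs, length.out = n + 1)[seq_len(n)]
  f[f > fs / 2] <- fs - f[f > fs / 2]
  g <- as.numeric(f > 0 & f <= f_max)
  z <- Re(stats::fft(g * stats::fft(w), inverse = TRUE)) / n
  z <- z / stats::sd(z)
  pmax(1 + 0.4 * z, 0.05)
}

#' Generate a phase-coupled narrowband pair
#'
#' Two narrowband series whose instantaneous phase difference has circular
#' mean `phase_lag`.  The second series is a cosine injection of the first
#' series' instantaneous phase, shifted by the lag, mixed with an
#' independent narrowband realization at weight `1 - strength`: at
#' `strength = 1` the lag is constant (PLV of the pair is 1), at
#' `strength = 0` the series are independent.
#'
#' @param band Band as `c(lo, hi)` in Hz or a one-row band table.
#' @param phase_lag Planted phase lag in radians (x leads y by this much).
#' @param strength Coupling strength in \[0, 1\].
#' @param fs Sampling rate (Hz).
#' @param n Number of samples.
#' @param seed Optional integer seed.
#' @return A list with numeric `x` and `y`.
#' @export
generate_coupled_pair <- function(band, phase_lag, strength, fs, n,
                                  seed = NULL) {
  b <- as_band(band)
  if (b["hi"] >= fs / 2)
    stop("band edge at or above the Nyquist frequency (fs/2 = ", fs / 2,
         " Hz)")
  stopifnot(strength >= 0, strength <= 1)
  with_seed(seed, {
    o1 <- narrowband_oscillation(b["lo"], b["hi"], fs, n)
    # the injection rides on its own slow envelope: the slow-amplitude x
    # smooth-phase factorization keeps the instantaneous phase of the
    # product exactly phi1 - lag while the envelopes of x and y stay
    # independent; the independent mixture component is a filtered-noise
    # realization, whose phase decorrelates quickly
    f_mod <- max((b["hi"] - b["lo"]) / 6, 2 / (n / fs))
    inj <- slow_envelope(n, fs, f_max = f_mod) * cos(o1$phase - phase_lag)
    indep <- narrowband_noise(b["lo"], b["hi"], fs, n)
    x <- o1$x / stats::sd(o1$x)
    y <- strength * inj / stats::sd(inj) + (1 - strength) * indep
    list(x = x, y = y)
  })
}

#' Generate a phase-amplitude coupled pair
#'
#' The phase of a low-frequency oscillation in series `x` modulates the
#' high-frequency envelope of series `y`: the HF envelope equals
#' `1 + depth * cos(phi_LF(t) - mod_lag)` on a unit-amplitude HF carrier.
#' `depth = 0` leaves the HF amplitude independent of the LF phase.
#'
#' @param lf,hf Low/high band as `c(lo, hi)` or one-row band tables; the
#'   bands must not overlap (`lf` hi edge at or below `hf` lo edge).
#' @param depth Modulation depth in \[0, 1\].
#' @param mod_lag Phase lag of the modulation in radians.
#' @inheritParams generate_coupled_pair
#' @return A list with numeric `x` (LF series) and `y` (modulated HF
#'   series).
#' @export
generate_pac_pair <- function(lf, hf, depth, mod_lag = 0, fs, n,
                              seed = NULL) {
  l <- as_band(lf); h <- as_band(hf)
  if (l["hi"] > h["lo"]) stop("overlapping bands: lf must precede hf")
  if (h["hi"] >= fs / 2)
    stop("band edge at or above the Nyquist frequency (fs/2 = ", fs / 2,
         " Hz)")
  stopifnot(depth >= 0, depth <= 1)
  with_seed(seed, {
    o_lf <- narrowband_oscillation(l["lo"], l["hi"], fs, n)
    o_hf <- narrowband_oscillation(h["lo"], h["hi"], fs, n)
    # carrier keeps its own slowly fluctuating envelope, so even at
    # depth 0 the HF envelope is a live (if unmodulated) signal
    y <- (1 + depth * cos(o_lf$phase - mod_lag)) * o_hf$x
    list(x = o_lf$x / stats::sd(o_lf$x), y = y / stats::sd(y))
  })
}

#' Generate a shared-envelope pair
#'
#' Two band-limited series (tone carriers at the band centers, so the
#' measured Hilbert envelope tracks the planted one) whose slow amplitude
#' envelopes share a common component with mixing weight `rho`:
#' `rho = 1` gives identical envelopes, `rho = 0` independent ones.
#'
#' @param band_a,band_b Bands as `c(lo, hi)` or one-row band tables.
#' @param rho Envelope mixing weight in \[0, 1\].
#' @inheritParams generate_coupled_pair
#' @return A list with numeric `x` and `y`.
#' @export
generate_env_pair <- function(band_a, band_b, rho, fs, n, seed = NULL) {
  a <- as_band(band_a); b <- as_band(band_b)
  if (max(a["hi"], b["hi"]) >= fs / 2)
    stop("band edge at or above the Nyquist frequency (fs/2 = ", fs / 2,
         " Hz)")
  stopifnot(rho >= 0, rho <= 1)
  with_seed(seed, {
    e <- slow_envelope(n, fs)
    e1 <- slow_envelope(n, fs)
    e2 <- slow_envelope(n, fs)
    t <- (seq_len(n) - 1) / fs
    ca <- cos(2 * pi * mean(a) * t + stats::runif(1, 0, 2 * pi))
    cb <- cos(2 * pi * mean(b) * t + stats::runif(1, 0, 2 * pi))
    # sqrt weights mix the envelope *variances* at rho : (1 - rho), so the
    # measured envelope correlation tracks rho approximately linearly
    list(x = (sqrt(rho) * e + sqrt(1 - rho) * e1) * ca,
         y = (sqrt(rho) * e + sqrt(1 - rho) * e2) * cb)
  })
}

#' Define a planted-coupling simulation plan
#'
#' A coupling plan fixes the ground truth of a synthetic cohort: number of
#' ROIs, band table, planted edges with their coupling mode and strength,
#' group-2 strength shifts, background-noise slope and signal-to-noise
#' ratio.
#'
#' @param n_rois Number of ROIs (channels); default 20.
#' @param bands Band table, see [default_bands()].
#' @param edges Tibble of planted edges with columns `roi_i`, `roi_j`,
#'   `kind` ("intra", "pac" or "env"), `band_a`, `band_b` (equal for
#'   intra), `strength` in \[0, 1\], `phase_lag` (radians; modulation lag
#'   for "pac", ignored for "env") and optionally `delta_strength` (added
#'   to `strength` for group-2 subjects; default 0).
#' @param noise_exponent 1/f slope of the background noise (default 1).
#' @param snr Linear amplitude ratio of planted signals to background
#'   noise (default 1).
#' @param seed Master seed for cohort generation (default 1).
#' @return A `coupling_plan` object.
#' @export
coupling_plan <- function(n_rois = 20, bands = default_bands(),
                          edges = NULL, noise_exponent = 1, snr = 1,
                          seed = 1) {
  bands <- validate_bands(bands)
  if (is.null(edges))
    edges <- tibble::tibble(roi_i = integer(), roi_j = integer(),
                            kind = character(), band_a = character(),
                            band_b = character(), strength = numeric(),
                            phase_lag = numeric(),
                            delta_strength = numeric())
  edges <- tibble::as_tibble(edges)
  if (!"delta_strength" %in% names(edges)) edges$delta_strength <- 0
  if (!"phase_lag" %in% names(edges)) edges$phase_lag <- 0
  if (nrow(edges)) {
    stopifnot(all(edges$roi_i != edges$roi_j),
              all(edges$roi_i >= 1), all(edges$roi_j <= n_rois),
              all(edges$strength >= 0), all(edges$strength <= 1),
              all(edges$kind %in% c("intra", "pac", "env")))
    bn <- as.character(bands$band)
    stopifnot(all(edges$band_a %in% bn), all(edges$band_b %in% bn))
    intra <- edges$kind == "intra"
    stopifnot(all(edges$band_a[intra] == edges$band_b[intra]))
    lo_a <- bands$lo[match(edges$band_a, bn)]
    lo_b <- bands$lo[match(edges$band_b, bn)]
    stopifnot(all(lo_a[edges$kind == "pac"] < lo_b[edges$kind == "pac"]))
  }
  if (snr <= 0) stop("snr must be positive")
  structure(list(n_rois = n_rois, bands = bands, edges = edges,
                 noise_exponent = noise_exponent, snr = snr,
                 seed = as.integer(seed)),
            class = "coupling_plan")
}

new_recording <- function(subject_id, group, data, fs, epoch_len_s) {
  stopifnot(length(dim(data)) == 3, !anyNA(data),
            dim(data)[3] == round(fs * epoch_len_s))
  structure(list(subject_id = subject_id, group = group, data = data,
                 fs = fs, epoch_len_s = epoch_len_s),
            class = "epoched_recording")
}

#' @export
print.epoched_recording <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<epoched_recording> %s (group %d): %d epochs x %d channels x %d samples @ %g Hz\n",
    x$subject_id, x$group, d[1], d[2], d[3], x$fs))
  invisible(x)
}

simulate_edge_pair <- function(edge, bands, fs, n) {
  ba <- band_row(bands, edge$band_a)
  bb <- band_row(bands, edge$band_b)
  switch(edge$kind,
    intra = generate_coupled_pair(ba, edge$phase_lag, edge$strength, fs, n),
    pac   = generate_pac_pair(ba, bb, edge$strength, edge$phase_lag, fs, n),
    env   = generate_env_pair(ba, bb, edge$strength, fs, n))
}

#' Simulate a two-group cohort with planted coupling
#'
#' Generates epoched multichannel recordings for two groups on a common
#' 1/f background.  Each planted edge adds a generator pair (phase-coupled,
#' phase-amplitude coupled or shared-envelope, per its `kind`) to its two
#' ROIs; per-subject strengths are jittered (truncated normal, sd 0.05)
#' around the plan value, and group-2 subjects have `delta_strength` added
#' first.  Fully reproducible from the plan seed.
#'
#' @param plan A [coupling_plan()].
#' @param n_subjects_per_group Subjects per group (>= 2).
#' @param epochs Epochs per subject (default 20).
#' @param epoch_len_s Epoch length in seconds (default 4).
#' @param fs Sampling rate in Hz (default 250).
#' @return A list with `recordings` (list of `epoched_recording`) and
#'   `truth` (tibble of realized per-subject edge strengths).
#' @export
generate_cohort <- function(plan, n_subjects_per_group = 25, epochs = 20,
                            epoch_len_s = 4, fs = 250) {
  stopifnot(inherits(plan, "coupling_plan"))
  if (n_subjects_per_group < 2)
    stop("need at least 2 subjects per group for cross-validation")
  n <- round(fs * epoch_len_s)
  n_sub <- 2 * n_subjects_per_group
  with_seed(plan$seed, {
    subj_seeds <- sample.int(.Machine$integer.max - 1, n_sub)
    recs <- vector("list", n_sub)
    truth <- vector("list", n_sub)
    for (s in seq_len(n_sub)) {
      group <- if (s <= n_subjects_per_group) 1L else 2L
      id <- sprintf("S%03d", s)
      recs[[s]] <- with_seed(subj_seeds[s], {
        edges <- plan$edges
        if (nrow(edges)) {
          eff <- edges$strength +
            ifelse(group == 2L, edges$delta_strength, 0)
          eff <- pmin(1, pmax(0, eff + stats::rnorm(nrow(edges), 0, 0.05)))
          edges$strength <- eff
        }
        truth[[s]] <- if (nrow(edges))
          dplyr::mutate(edges, subject_id = id, group = group,
                        .before = 1) else NULL
        dat <- array(0, dim = c(epochs, plan$n_rois, n))
        for (ep in seq_len(epochs)) {
          for (ch in seq_len(plan$n_rois))
            dat[ep, ch, ] <- noise_1f(n, fs, plan$noise_exponent)
          # one low-frequency driver per (source ROI, band): PAC edges
          # sharing a source modulate their targets with the same
          # oscillation, so a region can drive several targets without
          # diluting its own phase
          lf_cache <- list()
          if (nrow(edges)) for (e in seq_len(nrow(edges))) {
            ed <- edges[e, ]
            if (ed$kind == "pac") {
              l <- as_band(band_row(plan$bands, ed$band_a))
              h <- as_band(band_row(plan$bands, ed$band_b))
              key <- paste(ed$roi_i, ed$band_a)
              if (is.null(lf_cache[[key]])) {
                o <- narrowband_oscillation(l["lo"], l["hi"], fs, n)
                lf_cache[[key]] <- o
                dat[ep, ed$roi_i, ] <- dat[ep, ed$roi_i, ] +
                  plan$snr * o$x / stats::sd(o$x)
              }
              o_lf <- lf_cache[[key]]
              o_hf <- narrowband_oscillation(h["lo"], h["hi"], fs, n)
              y <- (1 + ed$strength * cos(o_lf$phase - ed$phase_lag)) *
                o_hf$x
              dat[ep, ed$roi_j, ] <- dat[ep, ed$roi_j, ] +
                plan$snr * y / stats::sd(y)
            } else {
              pr <- simulate_edge_pair(ed, plan$bands, fs, n)
              dat[ep, ed$roi_i, ] <- dat[ep, ed$roi_i, ] + plan$snr * pr$x
              dat[ep, ed$roi_j, ] <- dat[ep, ed$roi_j, ] + plan$snr * pr$y
            }
          }
        }
        new_recording(id, group, dat, fs, epoch_len_s)
      })
    }
    list(recordings = recs, truth = dplyr::bind_rows(truth))
  })
}

#' Simulate a voxel cluster around a true source
#'
#' Stands in for the cloud of beamformed source series inside one atlas
#' region: every voxel carries the true source scaled by a
#' distance-decaying gain plus independent Gaussian noise at the stated
#' per-voxel signal-to-noise ratio.  Voxel 1 is placed exactly at the
#' coordinate centroid of the cluster.
#'
#' @param true_source Numeric vector, the noise-free regional series.
#' @param n_voxels Number of voxels (>= 2).
#' @param snr Per-voxel linear amplitude SNR (> 0; `Inf` for noise-free).
#' @param spread_mm Spatial spread of the cluster (mm), also the gain
#'   decay length.
#' @param seed Optional integer seed.
#' @return A `voxel_cluster`: list with `voxel_series` (voxels x samples),
#'   `voxel_coords` (voxels x 3, mm) and `true_source`.
#' @export
generate_roi_voxels <- function(true_source, n_voxels, snr = 1,
                                spread_mm = 5, seed = NULL) {
  if (n_voxels < 2) stop("need at least 2 voxels")
  if (snr <= 0) stop("snr must be positive")
  with_seed(seed, {
    rest <- matrix(stats::rnorm(3 * (n_voxels - 1), sd = spread_mm),
                   ncol = 3)
    first <- colMeans(rest)      # so that voxel 1 sits at the centroid
    xyz <- rbind(first, rest)
    rownames(xyz) <- NULL
    d <- sqrt(rowSums(sweep(xyz, 2, colMeans(xyz))^2))
    gain <- exp(-d / spread_mm)
    sdt <- stats::sd(true_source)
    vs <- t(vapply(seq_len(n_voxels), function(v) {
      noise <- if (is.finite(snr))
        stats::rnorm(length(true_source), sd = gain[v] * sdt / snr)
      else 0
      gain[v] * true_source + noise
    }, numeric(length(true_source))))
    structure(list(voxel_series = vs, voxel_coords = xyz,
                   true_source = true_source),
              class = "voxel_cluster")
  })
}
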
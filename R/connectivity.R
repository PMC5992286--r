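as_epoch_matrix <- function(x) {
  if (is.matrix(x)) x else matrix(x, nrow = 1)
}

check_pair <- function(x, y) {
  if (length(x) != length(y)) stop("phase/envelope series length mismatch")
  if (NCOL(x) < 2 && length(x) < 2) stop("need at least 2 samples")
}

#' Phase-locking value
#'
#' PLV = |mean over t of exp(i (phi_x - phi_y))|, computed per epoch and
#' averaged across epochs.  1 for any constant phase lag, near 0 for
#' independent phases.
#'
#' @param phi_x,phi_y Instantaneous phase series in radians: vectors (one
#'   epoch) or matrices with epochs in rows.
#' @return Scalar in \[0, 1\].
#' @export
plv <- function(phi_x, phi_y) {
  check_pair(phi_x, phi_y)
  px <- as_epoch_matrix(phi_x); py <- as_epoch_matrix(phi_y)
  mean(Mod(rowMeans(exp(1i * (px - py)))))
}

#' Imaginary part of the phase-locking value
#'
#' iPLV = |Im mean exp(i (phi_x - phi_y))|, per epoch, averaged across
#' epochs.  Insensitive to zero-lag coupling (iPLV = 0 at constant zero
#' lag), hence resistant to volume-conduction artifacts; for a constant
#' lag d it equals |sin d|.  Always satisfies 0 <= iPLV <= PLV <= 1.
#'
#' @inheritParams plv
#' @return Scalar in \[0, 1\].
#' @export
iplv <- function(phi_x, phi_y) {
  check_pair(phi_x, phi_y)
  px <- as_epoch_matrix(phi_x); py <- as_epoch_matrix(phi_y)
  mean(abs(Im(rowMeans(exp(1i * (px - py))))))
}

#' Amplitude-envelope correlation
#'
#' Absolute Pearson correlation of two amplitude-envelope series, per
#' epoch, averaged across epochs (non-orthogonalized).  The absolute value
#' keeps weights non-negative for downstream graph filtering.
#'
#' @param env_x,env_y Envelope series: vectors or matrices with epochs in
#'   rows.
#' @return Scalar in \[0, 1\].
#' @export
corr_env <- function(env_x, env_y) {
  check_pair(env_x, env_y)
  ex <- as_epoch_matrix(env_x); ey <- as_epoch_matrix(env_y)
  vals <- vapply(seq_len(nrow(ex)), function(ep) {
    a <- ex[ep, ]; b <- ey[ep, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0)
      stop("zero-variance envelope: correlation undefined")
    abs(stats::cor(a, b))
  }, numeric(1))
  mean(vals)
}

#' Phase-amplitude coupling via the imaginary (or full) PLV
#'
#' Pipeline for one direction (x modulates y): band-pass x in the low
#' band and take its instantaneous phase; band-pass y in the high band and
#' take its amplitude envelope; band-pass that envelope within the low
#' band and take the phase of its analytic signal; return the phase
#' synchronization (iPLV by default) between the two phase series.  Edge
#' transients are trimmed before synchronization.
#'
#' @param x,y Raw (broadband) series: vectors or epoch-by-sample matrices.
#' @param lf,hf Low/high bands as `c(lo, hi)` or one-row band tables;
#'   must not overlap.
#' @param fs Sampling rate (Hz).
#' @param sync Synchronization index, `"iplv"` (default) or `"plv"`.
#' @param trim_s Seconds trimmed from each epoch end (default 0.5).
#' @return Scalar coupling weight in \[0, 1\].
#' @export
pac_iplv <- function(x, y, lf, hf, fs, sync = c("iplv", "plv"),
                     trim_s = 0.5) {
  sync <- match.arg(sync)
  l <- as_band(lf); h <- as_band(hf)
  if (l["hi"] > h["lo"]) stop("overlapping bands: lf must precede hf")
  xm <- as_epoch_matrix(x); ym <- as_epoch_matrix(y)
  vals <- vapply(seq_len(nrow(xm)), function(ep) {
    phi_lf <- analytic(bandpass(xm[ep, ], l["lo"], l["hi"], fs))$phase
    a_hf <- analytic(bandpass(ym[ep, ], h["lo"], h["hi"], fs))$envelope
    a_f <- bandpass(a_hf, l["lo"], l["hi"], fs)
    # a near-constant HF envelope leaves only filter ripple in the low
    # band; its phase is meaningless, so reject rather than report noise
    if (stats::sd(trim_edges(a_f, fs, trim_s)) <
        0.025 * mean(trim_edges(a_hf, fs, trim_s)))
      stop("degenerate phase: HF envelope carries no low-frequency ",
           "modulation")
    phi_mod <- analytic(a_f)$phase
    p1 <- trim_edges(phi_lf, fs, trim_s)
    p2 <- trim_edges(phi_mod, fs, trim_s)
    if (sync == "iplv") iplv(p2, p1) else plv(p2, p1)
  }, numeric(1))
  mean(vals)
}

#' Cross-frequency envelope correlation
#'
#' Absolute Pearson correlation between the envelope of `x` in the low
#' band and the envelope of `y` in the high band, per epoch, averaged.
#'
#' @inheritParams pac_iplv
#' @param band_a,band_b The two bands, low first.
#' @return Scalar in \[0, 1\].
#' @export
cfc_corr_env <- function(x, y, band_a, band_b, fs, trim_s = 0.5) {
  a <- as_band(band_a); b <- as_band(band_b)
  xm <- as_epoch_matrix(x); ym <- as_epoch_matrix(y)
  vals <- vapply(seq_len(nrow(xm)), function(ep) {
    ea <- trim_edges(analytic(bandpass(xm[ep, ], a["lo"], a["hi"],
                                       fs))$envelope, fs, trim_s)
    eb <- trim_edges(analytic(bandpass(ym[ep, ], b["lo"], b["hi"],
                                       fs))$envelope, fs, trim_s)
    corr_env(ea, eb)
  }, numeric(1))
  mean(vals)
}

new_sl_fcg <- function(W, estimator, mode_row, roi_labels = NULL) {
  stopifnot(isSymmetric(unname(W)), all(W >= 0), all(is.finite(W)),
            all(diag(W) == 0))
  if (is.null(roi_labels)) roi_labels <- sprintf("ROI%02d", seq_len(nrow(W)))
  dimnames(W) <- list(roi_labels, roi_labels)
  structure(list(W = W, estimator = estimator, mode = mode_row$mode,
                 kind = mode_row$kind, band_a = mode_row$band_a,
                 band_b = mode_row$band_b, roi_labels = roi_labels),
            class = "sl_fcg")
}

#' Wrap a weight matrix as a single-layer connectivity graph
#'
#' Constructor for `sl_fcg` objects from an existing weight matrix, e.g.
#' when assembling a multilayer graph from externally computed layers.
#'
#' @param W Symmetric non-negative weight matrix with zero diagonal.
#' @param estimator Estimator label (`"PLV"`, `"iPLV"`, `"CorrEnv"`).
#' @param mode Mode label as in [coupling_modes()] (e.g. `"alpha1"` or
#'   `"delta:gamma1"`).
#' @param bands Band table the mode refers to.
#' @return An `sl_fcg`.
#' @export
as_sl_fcg <- function(W, estimator, mode, bands = default_bands()) {
  md <- coupling_modes(bands)
  i <- match(mode, md$mode)
  if (is.na(i)) stop("unknown mode: ", mode)
  new_sl_fcg(W, estimator, md[i, ])
}

#' @export
print.sl_fcg <- function(x, ...) {
  cat(sprintf("<sl_fcg> %s / %s (%s): %d x %d, mean weight %.3f\n",
              x$estimator, x$mode, x$kind, nrow(x$W), ncol(x$W),
              mean(x$W[upper.tri(x$W)])))
  invisible(x)
}

symm_max <- function(D, how = "max") {
  W <- if (how == "max") pmax(D, t(D)) else (D + t(D)) / 2
  diag(W) <- 0
  W
}

# per-epoch band decomposition: phases and envelopes for the requested
# bands, returned untrimmed (PAC refilters the full-length envelope)
band_decompose <- function(X, bands, fs, which_bands = seq_len(nrow(bands))) {
  out <- vector("list", nrow(bands))
  for (b in which_bands) {
    Xf <- bandpass(X, bands$lo[b], bands$hi[b], fs)
    ph <- matrix(0, nrow(Xf), ncol(Xf)); en <- ph
    for (ch in seq_len(ncol(Xf))) {
      an <- analytic(Xf[, ch])
      ph[, ch] <- an$phase; en[, ch] <- an$envelope
    }
    out[[b]] <- list(phase = ph, env = en)
  }
  out
}

#' Build the single-layer connectivity graphs of one recording
#'
#' Computes, for one epoched recording, the full stack of single-layer
#' functional connectivity graphs: one per intra-frequency band and one
#' per ordered cross-frequency band pair (7 + 21 = 28 with the default
#' bands).  Estimators: `PLV`/`iPLV` use phase locking within bands and
#' the phase-amplitude coupling pipeline across bands; `CorrEnv` uses
#' amplitude-envelope correlation both within and across bands.  Cross
#' estimators are directional; the undirected graph entry is the maximum
#' (or mean) over the two direction assignments.  Each graph is estimated
#' per epoch and averaged across epochs.
#'
#' @param rec An `epoched_recording` (see [generate_cohort()]).
#' @param estimator `"iPLV"`, `"PLV"` or `"CorrEnv"`.
#' @param bands Band table (default [default_bands()]).
#' @param modes Optional subset of [coupling_modes()] rows to compute
#'   (default: all).
#' @param trim_s Seconds trimmed from each epoch end after filtering and
#'   Hilbert transform (default 0.5).
#' @param cfc_symmetrize `"max"` (default) or `"mean"` over the two
#'   direction assignments of cross-frequency estimators.
#' @return A named list of `sl_fcg` objects in fixed layer order.
#' @export
build_sl_fcgs <- function(rec, estimator = c("iPLV", "PLV", "CorrEnv"),
                          bands = default_bands(), modes = NULL,
                          trim_s = 0.5, cfc_symmetrize = c("max", "mean")) {
  estimator <- match.arg(estimator)
  cfc_symmetrize <- match.arg(cfc_symmetrize)
  stopifnot(inherits(rec, "epoched_recording"))
  bands <- validate_bands(bands, fs = rec$fs)
  all_modes <- coupling_modes(bands)
  if (is.null(modes)) modes <- all_modes
  n_ep <- dim(rec$data)[1]; n_ch <- dim(rec$data)[2]
  bidx <- function(nm) match(nm, as.character(bands$band))
  acc <- rep(list(matrix(0, n_ch, n_ch)), nrow(modes))

  for (ep in seq_len(n_ep)) {
    X <- t(rec$data[ep, , , drop = TRUE])      # samples x channels
    needed <- unique(c(bidx(modes$band_a), bidx(modes$band_b)))
    dec <- band_decompose(X, bands, fs = rec$fs, which_bands = needed)
    for (m in seq_len(nrow(modes))) {
      mode <- modes[m, ]
      W <- tryCatch({
        if (mode$kind == "intra") {
          b <- bidx(mode$band_a)
          if (estimator == "CorrEnv") {
            E <- trim_edges(dec[[b]]$env, rec$fs, trim_s)
            W <- abs(stats::cor(E)); diag(W) <- 0; W
          } else {
            P <- trim_edges(dec[[b]]$phase, rec$fs, trim_s)
            Z <- exp(1i * P)
            M <- t(Z) %*% Conj(Z) / nrow(P)
            W <- if (estimator == "PLV") Mod(M) else abs(Im(M))
            diag(W) <- 0
            (W + t(W)) / 2                     # exact symmetry
          }
        } else {
          a <- bidx(mode$band_a); b <- bidx(mode$band_b)
          if (estimator == "CorrEnv") {
            Ea <- trim_edges(dec[[a]]$env, rec$fs, trim_s)
            Eb <- trim_edges(dec[[b]]$env, rec$fs, trim_s)
            symm_max(abs(stats::cor(Ea, Eb)), cfc_symmetrize)
          } else {
            # phase of the HF envelope refiltered within the LF band
            Af <- bandpass(dec[[b]]$env, bands$lo[a], bands$hi[a], rec$fs)
            P2 <- matrix(0, nrow(Af), ncol(Af))
            for (ch in seq_len(ncol(Af)))
              P2[, ch] <- analytic(Af[, ch])$phase
            P1 <- trim_edges(dec[[a]]$phase, rec$fs, trim_s)
            P2 <- trim_edges(P2, rec$fs, trim_s)
            # directed: row = modulating channel (LF phase),
            # col = modulated channel (HF envelope phase)
            M <- t(exp(1i * P2)) %*% Conj(exp(1i * P1)) / nrow(P1)
            D <- if (estimator == "PLV") Mod(t(M)) else abs(Im(t(M)))
            symm_max(D, cfc_symmetrize)
          }
        }
      }, error = function(e)
        stop("estimator failed in mode ", mode$mode, ": ",
             conditionMessage(e), call. = FALSE))
      acc[[m]] <- acc[[m]] + W
    }
  }

  out <- lapply(seq_len(nrow(modes)), function(m)
    new_sl_fcg(acc[[m]] / n_ep, estimator, modes[m, ]))
  names(out) <- modes$mode
  out
}

#' Tidy edge table of connectivity graphs
#'
#' Vectorizes the upper triangle of one or more single-layer graphs into a
#' long tibble, the natural input of the edge-weight feature route.
#'
#' @param fcgs A single `sl_fcg` or a list of them.
#' @return A tibble with columns `mode`, `kind`, `roi_i`, `roi_j`,
#'   `weight`.
#' @export
fcg_edges <- function(fcgs) {
  if (inherits(fcgs, "sl_fcg")) fcgs <- list(fcgs)
  purrr::map_dfr(fcgs, function(g) {
    ut <- which(upper.tri(g$W), arr.ind = TRUE)
    tibble::tibble(mode = g$mode, kind = g$kind,
                   roi_i = ut[, 1], roi_j = ut[, 2],
                   weight = g$W[ut])
  })
}
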
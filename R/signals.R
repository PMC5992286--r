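#' Zero-phase Butterworth band-pass filter
#'
#' Forward-backward (zero-phase) third-order Butterworth band-pass, the
#' filterbank primitive applied to every channel before phase/envelope
#' extraction.
#'
#' @param x Numeric vector (one epoch of one channel) or a matrix with
#'   channels in columns.
#' @param lo,hi Band edges in Hz; `hi` must lie below `fs / 2`.
#' @param fs Sampling rate in Hz.
#' @return Filtered series, same length/shape as `x`.
#' @export
bandpass <- function(x, lo, hi, fs) {
  if (!is.finite(lo) || !is.finite(hi) || lo <= 0 || lo >= hi)
    stop("bands require 0 < lo < hi")
  if (hi >= fs / 2)
    stop("band edge ", hi, " Hz at or above the Nyquist frequency (fs/2 = ",
         fs / 2, " Hz)")
  bf <- signal::butter(3, c(lo, hi) / (fs / 2), type = "pass")
  if (is.matrix(x)) {
    apply(x, 2, function(col) as.numeric(signal::filtfilt(bf, col)))
  } else {
    as.numeric(signal::filtfilt(bf, x))
  }
}

#' Analytic signal: instantaneous phase and envelope
#'
#' Computes the analytic signal z(t) = x(t) + i H\[x\](t) via the FFT
#' construction of the Hilbert transform, and returns instantaneous phase
#' and amplitude envelope.  The caller is responsible for `x` being
#' narrowband (filter first); phase of a broadband signal is not
#' interpretable.
#'
#' @param x Numeric vector, a narrowband series.
#' @return A list with `phase` (radians, in (-pi, pi\]), `envelope`
#'   (non-negative) and `z` (the complex analytic series).
#' @export
analytic <- function(x) {
  if (anyNA(x)) stop("input contains NA")
  if (stats::sd(x) == 0)
    stop("constant input: instantaneous phase undefined")
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  z <- stats::fft(h * stats::fft(x), inverse = TRUE) / n
  list(phase = Arg(z), envelope = Mod(z), z = z)
}

#' Drop filter/Hilbert transients from epoch edges
#'
#' Zero-phase filtering and the Hilbert transform both distort a stretch of
#' samples at each epoch boundary; connectivity estimation discards
#' `trim_s` seconds from both ends.
#'
#' @param x Vector or matrix (samples in rows).
#' @param fs Sampling rate (Hz).
#' @param trim_s Seconds trimmed from each end (default 0.5).
#' @return The trimmed series.
#' @export
trim_edges <- function(x, fs, trim_s = 0.5) {
  k <- round(trim_s * fs)
  n <- if (is.matrix(x)) nrow(x) else length(x)
  if (2 * k >= n) stop("trim longer than the epoch")
  idx <- (k + 1):(n - k)
  if (is.matrix(x)) x[idx, , drop = FALSE] else x[idx]
}

#' First-principal-component ROI representative
#'
#' Reduces a cluster of per-voxel source series to one representative: the
#' first principal-component score series of the voxels-by-time matrix,
#' sign-aligned to correlate positively with the mean voxel series so the
#' result does not depend on the eigen-solver's sign convention.
#'
#' @param cluster A `voxel_cluster`, see [generate_roi_voxels()], or any
#'   list with a `voxel_series` matrix (voxels x samples).
#' @return Numeric vector, one representative series.
#' @seealso [roi_centroid()] for the centroid-voxel alternative.
#' @export
roi_pca <- function(cluster) {
  vs <- cluster$voxel_series
  stopifnot(is.matrix(vs), nrow(vs) >= 2)
  if (all(vs == 0)) stop("all-zero voxel cluster")
  # time in rows for prcomp; representative = first PC score series
  pc <- stats::prcomp(t(vs), center = TRUE, scale. = FALSE, rank. = 1)
  rep <- pc$x[, 1]
  m <- colMeans(vs)              # mean voxel series across voxels
  if (stats::sd(m) > 0 && stats::cor(rep, m) < 0) rep <- -rep
  as.numeric(rep)
}

#' Centroid-voxel ROI representative
#'
#' Returns, unmodified, the series of the voxel closest (Euclidean) to the
#' unweighted coordinate centroid of the cluster; ties break to the lowest
#' voxel index.
#'
#' @inheritParams roi_pca
#' @return Numeric vector, the selected voxel's series.
#' @export
roi_centroid <- function(cluster) {
  vs <- cluster$voxel_series
  xyz <- cluster$voxel_coords
  stopifnot(is.matrix(vs), is.matrix(xyz), nrow(xyz) == nrow(vs))
  if (any(!is.finite(xyz))) stop("voxel coordinates must be finite")
  ctr <- colMeans(xyz)
  d2 <- rowSums(sweep(xyz, 2, ctr)^2)
  as.numeric(vs[which.min(d2), ])
}
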
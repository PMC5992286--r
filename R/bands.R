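#' Canonical frequency bands
#'
#' The seven-band decomposition used throughout the package: delta
#' (0.5--4 Hz), theta (4--8), alpha1 (8--10), alpha2 (10--13), beta1
#' (13--20), beta2 (20--30) and gamma1 (30--45 Hz).
#'
#' @return A tibble with columns `band` (ordered factor), `lo` and `hi`
#'   (band edges in Hz).
#' @examples
#' default_bands()
#' @export
default_bands <- function() {
  tibble::tibble(
    band = band_levels(),
    lo = c(0.5, 4, 8, 10, 13, 20, 30),
    hi = c(4, 8, 10, 13, 20, 30, 45)
  )
}

band_levels <- function() {
  factor(c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2", "gamma1"),
         levels = c("delta", "theta", "alpha1", "alpha2", "beta1", "beta2",
                    "gamma1"), ordered = TRUE)
}

#' Validate a band table
#'
#' @param bands A data frame with columns `band`, `lo`, `hi`.
#' @param fs Optional sampling rate (Hz); if given, every `hi` must lie
#'   strictly below the Nyquist frequency `fs / 2`.
#' @return The validated band tibble, invisibly coerced.
#' @export
validate_bands <- function(bands, fs = NULL) {
  stopifnot(is.data.frame(bands))
  missing <- setdiff(c("band", "lo", "hi"), names(bands))
  if (length(missing))
    stop("band table lacks column(s): ", paste(missing, collapse = ", "))
  if (any(!is.finite(bands$lo)) || any(!is.finite(bands$hi)))
    stop("band edges must be finite")
  if (any(bands$lo <= 0) || any(bands$lo >= bands$hi))
    stop("bands require 0 < lo < hi")
  if (!is.null(fs) && any(bands$hi >= fs / 2))
    stop("band edge at or above the Nyquist frequency (fs/2 = ",
         fs / 2, " Hz)")
  tibble::as_tibble(bands)
}

#' Enumerate coupling modes
#'
#' For B bands there are B intra-frequency modes and choose(B, 2)
#' cross-frequency modes (low band modulating / co-varying with the high
#' band), enumerated in fixed band order.  With the default seven bands
#' this yields 7 intra + 21 cross = 28 modes, the layer order of the
#' multilayer graph.
#'
#' @param bands Band table, see [default_bands()].
#' @return A tibble with columns `mode` (label), `kind` ("intra" or
#'   "cross"), `band_a`, `band_b` (band names; equal for intra modes) and
#'   `layer` (1-based position in the fixed layer order).
#' @examples
#' coupling_modes()          # 28 rows
#' @export
coupling_modes <- function(bands = default_bands()) {
  bands <- validate_bands(bands)
  nm <- as.character(bands$band)
  intra <- tibble::tibble(kind = "intra", band_a = nm, band_b = nm)
  idx <- utils::combn(seq_along(nm), 2)
  cross <- tibble::tibble(kind = "cross",
                          band_a = nm[idx[1, ]],
                          band_b = nm[idx[2, ]])
  out <- dplyr::bind_rows(intra, cross)
  out$mode <- ifelse(out$kind == "intra", out$band_a,
                     paste0(out$band_a, ":", out$band_b))
  out$layer <- seq_len(nrow(out))
  out[, c("mode", "kind", "band_a", "band_b", "layer")]
}

#' Ordered cross-frequency band pairs
#'
#' @inheritParams coupling_modes
#' @return The cross-frequency subset of [coupling_modes()] (21 rows for
#'   seven bands), low band first.
#' @export
cfc_pairs <- function(bands = default_bands()) {
  dplyr::filter(coupling_modes(bands), .data$kind == "cross")
}

band_row <- function(bands, name) {
  i <- match(as.character(name), as.character(bands$band))
  if (is.na(i)) stop("unknown band: ", name)
  bands[i, ]
}
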
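# exact float round trip: 17 significant digits always re-read to the
# identical double
fmt_doubles <- function(df) {
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- sprintf("%.17g", df[[j]])
  df
}

#' Write / read a synthetic cohort as plain-text CSV
#'
#' One `subjects.csv` manifest (subject id, group, sampling rate, epoch
#' length, dimensions) plus one CSV per subject holding the epoch-by-
#' channel sample rows.  Values round-trip exactly (17 significant
#' digits).
#'
#' @param cohort A list with `recordings` and optionally `truth`, as
#'   returned by [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  recs <- cohort$recordings
  manifest <- purrr::map_dfr(recs, function(r)
    tibble::tibble(subject_id = r$subject_id, group = r$group, fs = r$fs,
                   epoch_len_s = r$epoch_len_s,
                   epochs = dim(r$data)[1], channels = dim(r$data)[2],
                   samples = dim(r$data)[3]))
  readr::write_csv(manifest, file.path(dir, "subjects.csv"))
  for (r in recs) {
    d <- dim(r$data)
    flat <- matrix(0, d[1] * d[2], d[3])
    for (e in seq_len(d[1])) for (ch in seq_len(d[2]))
      flat[(e - 1) * d[2] + ch, ] <- r$data[e, ch, ]
    df <- tibble::as_tibble(flat, .name_repair = ~ paste0("s", seq_len(d[3])))
    df <- dplyr::mutate(df,
                        epoch = rep(seq_len(d[1]), each = d[2]),
                        channel = rep(seq_len(d[2]), times = d[1]),
                        .before = 1)
    readr::write_csv(fmt_doubles(df), file.path(dir, paste0(r$subject_id, ".csv")))
  }
  if (!is.null(cohort$truth) && nrow(cohort$truth))
    readr::write_csv(cohort$truth, file.path(dir, "truth.csv"))
  invisible(dir)
}

#' @rdname write_cohort
#' @return For `read_cohort`: the cohort list (`recordings`, `truth`).
#' @export
read_cohort <- function(dir) {
  mf <- file.path(dir, "subjects.csv")
  if (!file.exists(mf)) stop("not a cohort directory: missing ", mf)
  manifest <- readr::read_csv(mf, show_col_types = FALSE)
  need <- c("subject_id", "group", "fs", "epoch_len_s", "epochs",
            "channels", "samples")
  miss <- setdiff(need, names(manifest))
  if (length(miss))
    stop("malformed cohort manifest: missing column(s) ",
         paste(miss, collapse = ", "))
  recs <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i, ]
    path <- file.path(dir, paste0(m$subject_id, ".csv"))
    if (!file.exists(path)) stop("missing subject file: ", path)
    # read as character and convert via strtod: exact to the last bit
    df <- readr::read_csv(path, col_types = readr::cols(.default = "c"))
    if (nrow(df) != m$epochs * m$channels ||
        ncol(df) != m$samples + 2)
      stop("malformed or truncated subject file: ", path)
    dat <- array(0, dim = c(m$epochs, m$channels, m$samples))
    vals <- matrix(as.numeric(as.matrix(df[, -(1:2)])), nrow = nrow(df))
    ep <- as.integer(df$epoch); ch <- as.integer(df$channel)
    for (k in seq_len(nrow(df)))
      dat[ep[k], ch[k], ] <- vals[k, ]
    new_recording(m$subject_id, as.integer(m$group), dat, m$fs,
                  m$epoch_len_s)
  })
  truth_path <- file.path(dir, "truth.csv")
  truth <- if (file.exists(truth_path))
    readr::read_csv(truth_path, show_col_types = FALSE) else NULL
  list(recordings = recs, truth = truth)
}

#' Write / read a weight matrix as a TSV edge list
#'
#' Upper-triangle positive-weight edges as `roi_i`, `roi_j`, `weight`
#' rows; reading rebuilds the exact symmetric matrix.
#'
#' @param W Symmetric weight matrix or an `sl_fcg`.
#' @param path Output TSV path.
#' @export
write_edge_list <- function(W, path) {
  if (inherits(W, "sl_fcg")) W <- W$W
  check_weight_matrix(W)
  ut <- which(upper.tri(W) & W != 0, arr.ind = TRUE)
  readr::write_tsv(fmt_doubles(tibble::tibble(roi_i = ut[, 1], roi_j = ut[, 2],
                                              weight = W[ut])),
                   path)
  invisible(path)
}

#' @rdname write_edge_list
#' @param n_rois Matrix side (edge lists do not record isolated nodes).
#' @return For `read_edge_list`: the reconstructed matrix.
#' @export
read_edge_list <- function(path, n_rois) {
  ed <- readr::read_tsv(path, col_types = readr::cols(.default = "c"))
  miss <- setdiff(c("roi_i", "roi_j", "weight"), names(ed))
  if (length(miss))
    stop("malformed edge list ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  W <- matrix(0, n_rois, n_rois)
  i <- as.integer(ed$roi_i); j <- as.integer(ed$roi_j)
  w <- as.numeric(ed$weight)   # strtod: exact round trip
  W[cbind(i, j)] <- w
  W[cbind(j, i)] <- w
  W
}

config_defaults <- function() {
  list(n_rois = 20, fs = 250, epoch_len_s = 4, epochs = 20,
       n_subjects_per_group = 25, estimator = "iPLV", scheme = "kfold",
       routes = "edge", roi_representation = "pca", modes = "all",
       k_rank = 15, m_consensus = 15, d1 = 6, d2 = 6, k_folds = 5,
       snr = 1, noise_exponent = 1, seed = 1)
}

#' Read and validate a pipeline configuration
#'
#' Reads a YAML configuration, fills defaults, and validates it against
#' the schema before any computation; errors name the offending field.
#' Band entries, if given, must each provide `band`, `lo` and `hi`.
#'
#' @param path YAML file path, or a list already in memory.
#' @return A validated config list with a `bands` tibble and an `edges`
#'   tibble of planted couplings.
#' @export
read_config <- function(path) {
  cfg <- if (is.list(path)) path else yaml::read_yaml(path)
  base <- config_defaults()
  unknown <- setdiff(names(cfg),
                     c(names(base), "bands", "edges", "cfc_symmetrize"))
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  out <- utils::modifyList(base, cfg[names(cfg) %in% names(base)])
  if (!is.null(cfg$bands)) {
    bd <- purrr::map_dfr(cfg$bands, function(b) {
      miss <- setdiff(c("band", "lo", "hi"), names(b))
      if (length(miss))
        stop("config field 'bands': entry missing ",
             paste(miss, collapse = ", "))
      tibble::as_tibble(b)
    })
    out$bands <- validate_bands(bd)
  } else out$bands <- default_bands()
  out$edges <- if (!is.null(cfg$edges))
    purrr::map_dfr(cfg$edges, tibble::as_tibble) else NULL
  if (!out$estimator %in% c("iPLV", "PLV", "CorrEnv"))
    stop("config field 'estimator' must be iPLV, PLV or CorrEnv")
  if (!out$scheme %in% c("loocv", "kfold"))
    stop("config field 'scheme' must be loocv or kfold")
  if (!out$modes %in% c("all", "intra"))
    stop("config field 'modes' must be all or intra")
  for (f in c("fs", "epoch_len_s", "epochs", "n_rois",
              "n_subjects_per_group", "seed"))
    if (!is.numeric(out[[f]]) || length(out[[f]]) != 1)
      stop("config field '", f, "' must be a single number")
  validate_bands(out$bands, fs = out$fs)
  out
}

#' Write cross-validation results as CSV
#'
#' One row per result (scheme x route), via [glance.cv_result()].
#'
#' @param results A `cv_result` or list of them.
#' @param path Output CSV path.
#' @export
write_cv_results <- function(results, path) {
  if (inherits(results, "cv_result")) results <- list(results)
  readr::write_csv(purrr::map_dfr(results, glance), path)
  invisible(path)
}
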
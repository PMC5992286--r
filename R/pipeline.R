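read_subject_graphs <- function(path, estimator, modes_tbl, n_rois) {
  ed <- readr::read_tsv(path, show_col_types = FALSE)
  gs <- lapply(seq_len(nrow(modes_tbl)), function(m) {
    sub <- ed[ed$mode == modes_tbl$mode[m], ]
    W <- matrix(0, n_rois, n_rois)
    W[cbind(sub$roi_i, sub$roi_j)] <- sub$weight
    W[cbind(sub$roi_j, sub$roi_i)] <- sub$weight
    new_sl_fcg(W, estimator, modes_tbl[m, ])
  })
  names(gs) <- modes_tbl$mode
  gs
}

#' Run the full simulate -> connect -> filter -> metrics -> classify
#' pipeline
#'
#' Orchestrates the package end to end from one validated configuration:
#' simulate (or read) a cohort, build the single-layer connectivity
#' graphs per subject, OMST-filter them, compute the multilayer
#' participation coefficient and the group comodulograms, and
#' cross-validate the configured classification routes.  All randomness
#' flows from the config seed; a run with the same config and seed writes
#' identical CSV outputs.  Per-stage artifacts are written under
#' `out_dir` and reused on re-runs (`overwrite = TRUE` forces
#' recomputation), together with the resolved configuration and a run
#' log.
#'
#' @param config A YAML path or config list, see [read_config()].
#' @param out_dir Output directory for per-stage artifacts.
#' @param cohort Optional pre-built cohort (as from [generate_cohort()]
#'   or [read_cohort()]); by default one is simulated from the config.
#' @param stages Character vector of stages to run, a subset of
#'   `c("simulate", "connect", "omst", "mpc", "comodulogram",
#'   "classify")` (default: all, in order).
#' @param overwrite Recompute stages whose artifacts already exist
#'   (default `FALSE`).
#' @return A list with the per-stage results that were run: `cohort`,
#'   `graphs`, `omst`, `mpc`, `comodulograms`, `cv`.
#' @export
run_pipeline <- function(config, out_dir,
                         cohort = NULL,
                         stages = c("simulate", "connect", "omst", "mpc",
                                    "comodulogram", "classify"),
                         overwrite = FALSE) {
  cfg <- read_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  logf <- function(...) {
    msg <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                   sprintf(...))
    cat(msg, "\n", file = log_path, append = TRUE, sep = "")
  }
  yaml::write_yaml(cfg[setdiff(names(cfg), c("bands", "edges"))],
                   file.path(out_dir, "config_resolved.yaml"))
  logf("run started; mlfcg %s, R %s",
       as.character(utils::packageVersion("mlfcg")),
       paste(R.version$major, R.version$minor, sep = "."))
  res <- list()

  if ("simulate" %in% stages && is.null(cohort)) {
    cdir <- file.path(out_dir, "cohort")
    if (!overwrite && file.exists(file.path(cdir, "subjects.csv"))) {
      logf("simulate: reusing cached cohort")
      cohort <- read_cohort(cdir)
    } else {
      plan <- coupling_plan(n_rois = cfg$n_rois, bands = cfg$bands,
                            edges = cfg$edges,
                            noise_exponent = cfg$noise_exponent,
                            snr = cfg$snr, seed = cfg$seed)
      cohort <- generate_cohort(plan, cfg$n_subjects_per_group,
                                epochs = cfg$epochs,
                                epoch_len_s = cfg$epoch_len_s,
                                fs = cfg$fs)
      write_cohort(cohort, cdir)
      logf("simulate: %d subjects written", length(cohort$recordings))
    }
  }
  if (is.null(cohort)) stop("no cohort: supply one or include 'simulate'")
  res$cohort <- cohort
  recs <- cohort$recordings
  y <- factor(vapply(recs, function(r) r$group, integer(1)))

  modes_tbl <- coupling_modes(cfg$bands)
  if (cfg$modes == "intra")
    modes_tbl <- dplyr::filter(modes_tbl, .data$kind == "intra")

  graphs <- NULL
  if (any(c("connect", "omst", "mpc", "comodulogram", "classify")
          %in% stages)) {
    gdir <- file.path(out_dir, "graphs")
    dir.create(gdir, showWarnings = FALSE)
    graphs <- lapply(recs, function(r) {
      cached <- file.path(gdir, paste0(r$subject_id, "_",
                                       cfg$estimator, ".tsv"))
      if (!overwrite && file.exists(cached))
        return(read_subject_graphs(cached, cfg$estimator, modes_tbl,
                                   cfg$n_rois))
      gs <- build_sl_fcgs(r, estimator = cfg$estimator, bands = cfg$bands,
                          modes = modes_tbl)
      readr::write_tsv(fcg_edges(gs), cached)
      gs
    })
    names(graphs) <- vapply(recs, function(r) r$subject_id, character(1))
    res$graphs <- graphs
    logf("connect: %d graphs x %d subjects (%s)", nrow(modes_tbl),
         length(graphs), cfg$estimator)
  }

  if ("omst" %in% stages || "mpc" %in% stages) {
    omst_layers <- lapply(graphs, function(gs)
      lapply(gs, function(g) omst_filter(g$W)$W_filtered))
    res$omst <- omst_layers
    logf("omst: per-layer filtering done")
    if ("mpc" %in% stages) {
      mpcs <- lapply(omst_layers, mpc)
      mtab <- purrr::imap_dfr(mpcs, function(m, id)
        dplyr::mutate(tidy(m), subject_id = id, .before = 1))
      readr::write_csv(mtab, file.path(out_dir, "mpc.csv"))
      res$mpc <- mpcs
      logf("mpc: written mpc.csv")
    }
  }

  if ("comodulogram" %in% stages && cfg$modes != "all") {
    logf("comodulogram: skipped (requires modes = 'all')")
    stages <- setdiff(stages, "comodulogram")
  }
  if ("comodulogram" %in% stages) {
    comods <- lapply(graphs, function(gs) {
      ml <- assemble_mlfcg(gs, bands = cfg$bands)
      comodulogram(omst_filter(ml$flattened), n_rois = cfg$n_rois,
                   bands = cfg$bands)
    })
    for (grp in levels(y)) {
      avg <- average_comodulograms(comods[y == grp])
      readr::write_csv(tidy(avg),
                       file.path(out_dir,
                                 paste0("comodulogram_group", grp, ".csv")))
    }
    res$comodulograms <- comods
    logf("comodulogram: group averages written")
  }

  if ("classify" %in% stages) {
    cvs <- list()
    for (route in cfg$routes) {
      src <- switch(route,
        edge = edge_feature_matrix(graphs),
        tensor = lapply(graphs, function(gs) {
          stopifnot(length(gs) == 1 || cfg$modes == "all")
          if (length(gs) == 1) omst_filter(gs[[1]]$W)$W_filtered
          else assemble_mlfcg(gs, cfg$bands)$flattened
        }),
        mpc = {
          if (is.null(res$mpc)) stop("mpc route requires the mpc stage")
          t(vapply(res$mpc, function(m) m$per_node$mpc,
                   numeric(cfg$n_rois)))
        },
        stop("unknown route: ", route))
      cvs[[route]] <- crossvalidate(src, y, scheme = cfg$scheme,
                                    route = route, k_rank = cfg$k_rank,
                                    m_consensus = cfg$m_consensus,
                                    d1 = cfg$d1, d2 = cfg$d2,
                                    k_folds = cfg$k_folds,
                                    seed = cfg$seed)
    }
    write_cv_results(cvs, file.path(out_dir, "cv_results.csv"))
    res$cv <- cvs
    logf("classify: cv_results.csv written")
  }
  logf("run finished")
  res
}
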
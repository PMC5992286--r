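#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a cross-validation result
#'
#' @param x A `cv_result` from [crossvalidate()].
#' @param ... Unused.
#' @return Per-fold metrics tibble (k-fold) or the per-subject prediction
#'   tibble (LOOCV, where a per-fold table is a single subject).
#' @method tidy cv_result
#' @export
tidy.cv_result <- function(x, ...) {
  if (!is.null(x$per_fold)) x$per_fold else x$predictions
}

#' One-row summary of a cross-validation result
#'
#' @inheritParams tidy.cv_result
#' @return One-row tibble: scheme, route, accuracy, sensitivity,
#'   specificity with their across-fold standard deviations (NA for
#'   LOOCV, where metrics come from the pooled confusion matrix).
#' @method glance cv_result
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(scheme = x$scheme, route = x$route,
                 accuracy = x$metrics$accuracy,
                 accuracy_sd = x$metrics_sd$accuracy,
                 sensitivity = x$metrics$sensitivity,
                 sensitivity_sd = x$metrics_sd$sensitivity,
                 specificity = x$metrics$specificity,
                 specificity_sd = x$metrics_sd$specificity)
}

#' @rdname mpc
#' @param x An `mpc_result`.
#' @param ... Unused.
#' @method tidy mpc_result
#' @export
tidy.mpc_result <- function(x, ...) x$per_node

#' @rdname mpc
#' @method glance mpc_result
#' @export
glance.mpc_result <- function(x, ...) {
  tibble::tibble(global_mpc = x$global, n_nodes = nrow(x$per_node))
}

#' @rdname comodulogram
#' @param x A `comodulogram`.
#' @param ... Unused.
#' @method tidy comodulogram
#' @export
tidy.comodulogram <- function(x, ...) x$table

#' @rdname omst_filter
#' @param x An `omst_result`.
#' @param ... Unused.
#' @method tidy omst_result
#' @export
tidy.omst_result <- function(x, ...) x$J_curve

#' Plot the distribution of retained connections across coupling modes
#'
#' Heatmap of the comodulogram: intra-band cells on the diagonal,
#' cross-frequency pairs above it.
#'
#' @param object A `comodulogram`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot comodulogram
#' @export
autoplot.comodulogram <- function(object, ...) {
  tab <- object$table
  lv <- unique(c(tab$band_a, tab$band_b))
  tab$band_a <- factor(tab$band_a, levels = lv)
  tab$band_b <- factor(tab$band_b, levels = lv)
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$band_b, y = .data$band_a,
                                    fill = .data$pd)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$pd)), size = 3) +
    ggplot2::scale_y_discrete(limits = rev(lv)) +
    ggplot2::scale_fill_viridis_c(name = "P(edge)") +
    ggplot2::labs(x = "high / second band", y = "low / first band",
                  title = "Retained connections per coupling mode") +
    ggplot2::theme_minimal()
}

#' Plot the OMST quality curve
#'
#' Global efficiency minus cost (J) against cost, round by round, with
#' the selected peak marked.
#'
#' @param object An `omst_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot omst_result
#' @export
autoplot.omst_result <- function(object, ...) {
  cv <- object$J_curve
  ggplot2::ggplot(cv, ggplot2::aes(x = .data$cost, y = .data$J)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_point(data = cv[object$peak_round, ], colour = "red",
                        size = 3) +
    ggplot2::labs(x = "cost (fraction of total weight)",
                  y = "J = GE - cost",
                  title = "OMST quality curve") +
    ggplot2::theme_minimal()
}

#' Plot a single-layer connectivity graph as a heatmap
#'
#' @param object An `sl_fcg`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot sl_fcg
#' @export
autoplot.sl_fcg <- function(object, ...) {
  ed <- fcg_edges(object)
  ggplot2::ggplot(ed, ggplot2::aes(x = .data$roi_j, y = .data$roi_i,
                                   fill = .data$weight)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = object$estimator) +
    ggplot2::labs(title = paste0(object$estimator, " / ", object$mode),
                  x = "ROI", y = "ROI") +
    ggplot2::theme_minimal()
}
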
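#' Tidy a fitted model result
#'
#' One row per outer fold plus the pooled row, broom style.
#'
#' @param x A `sirt_model_result`.
#' @param ... Ignored.
#' @return Tibble with `fold` (`"pooled"` or the fold number), `auc`,
#'   `acc` and, for the pooled row, `sen`/`spe` and the bootstrap CI.
#' @exportS3Method generics::tidy
tidy.sirt_model_result <- function(x, ...) {
  dplyr::bind_rows(
    tibble::tibble(fold = "pooled", auc = x$auc, acc = x$acc,
                   sen = x$sen, spe = x$spe,
                   auc_lo = x$auc_ci[1], auc_hi = x$auc_ci[2]),
    dplyr::mutate(x$fold_metrics, fold = as.character(.data$fold),
                  sen = NA_real_, spe = NA_real_,
                  auc_lo = NA_real_, auc_hi = NA_real_))
}

#' One-line summary of a fitted model result
#'
#' @param x A `sirt_model_result`.
#' @param ... Ignored.
#' @return One-row tibble: strategy, fs, classifier, pooled metrics,
#'   confusion counts.
#' @exportS3Method generics::glance
glance.sirt_model_result <- function(x, ...) {
  tibble::tibble(strategy = as.character(x$strategy %||% NA),
                 fs = x$fs, classifier = x$classifier,
                 auc = x$auc, acc = x$acc, sen = x$sen, spe = x$spe,
                 tp = x$confusion["TP"], tn = x$confusion["TN"],
                 fp = x$confusion["FP"], fn = x$confusion["FN"],
                 n = length(x$labels), seed = x$seed)
}

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Heatmap of experiment metrics
#'
#' AUC (or another metric) per feature-selection method x classifier,
#' faceted by strategy category and subcategory.
#'
#' @param object A [run_experiment()] result.
#' @param metric Column to display (default `"auc"`).
#' @param ... Ignored.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.sirt_experiment <- function(object, metric = "auc", ...) {
  df <- dplyr::filter(object, .data$trained)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$classifier, y = .data$fs,
                                   fill = .data[[metric]])) +
    ggplot2::geom_tile() +
    ggplot2::facet_grid(category ~ subcategory) +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = "classifier", y = "feature selection",
                  fill = toupper(metric)) +
    ggplot2::theme_minimal(base_size = 9)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
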
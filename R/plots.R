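#' Heatmap of an intraslide correction map
#'
#' Displays the per-spot gradient correction (log2) over the full slide grid,
#' the visual counterpart of the local-median deviation maps used to judge
#' gradient strength.
#'
#' @param tab A [gradient_correct()] result (spot table with a `correction`
#'   column).
#' @return A ggplot object.
#' @export
plot_correction_map <- function(tab) {
  stopifnot("correction" %in% names(tab))
  ggplot2::ggplot(tab, ggplot2::aes(.data$x_um, -.data$y_um,
                                    fill = .data$correction)) +
    ggplot2::geom_tile(width = 500, height = 500) +
    ggplot2::scale_fill_gradient2(low = "red", mid = "white",
                                  high = "green4", midpoint = 0) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "correction\n(log2)",
                  title = "Intraslide gradient correction map") +
    ggplot2::theme_minimal()
}

#' @rdname plot_roc
#' @param object A `kinome_eval` object.
#' @param ... Unused.
#' @method autoplot kinome_eval
#' @export
autoplot.kinome_eval <- function(object, ...) plot_roc(object)

#' ROC curve of substrate classification
#'
#' @param ev A `kinome_eval` from [classify_and_roc()].
#' @return A ggplot object.
#' @export
plot_roc <- function(ev) {
  ggplot2::ggplot(ev$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC (AUC = %.3f)", ev$auc)) +
    ggplot2::theme_minimal()
}

#' Benchmark summary plot
#'
#' Mean AUC (with SEM error bars) per normalizer over the benchmark grid,
#' against a chosen grid variable.
#'
#' @param bench A [benchmark_normalizers()] result.
#' @param x Name of the grid column for the x axis.
#' @return A ggplot object.
#' @export
plot_benchmark <- function(bench, x) {
  ggplot2::ggplot(bench, ggplot2::aes(.data[[x]], .data$mean_auc,
                                      colour = .data$normalizer)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = .data$mean_auc - .data$sem_auc,
      ymax = .data$mean_auc + .data$sem_auc), width = 0) +
    ggplot2::labs(y = "Mean AUC", colour = "Normalizer") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
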
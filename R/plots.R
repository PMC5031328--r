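#' Plot methods for benchmark results
#'
#' `autoplot()` methods: a `roc_curve` draws TPR against FPR with the random
#' diagonal; a `pr_curve` draws precision against recall; an `auc_result`
#' shows the distribution of per-subset AUCs. `plot_score_distribution()`
#' overlays binder and non-binder score densities with the call threshold.
#'
#' @param object Object to plot.
#' @param ... Ignored.
#' @return A ggplot object.
#' @name pdz-plots
NULL

#' @rdname pdz-plots
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = "ROC curve") +
    ggplot2::theme_minimal()
}

#' @rdname pdz-plots
#' @export
autoplot.pr_curve <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$recall, y = .data$precision)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Recall", y = "Precision",
                  title = "Precision-recall curve") +
    ggplot2::theme_minimal()
}

#' @rdname pdz-plots
#' @export
autoplot.auc_result <- function(object, ...) {
  per <- tidyr::pivot_longer(object$per_subset,
                             c("roc_auc", "pr_auc"),
                             names_to = "curve", values_to = "auc")
  ggplot2::ggplot(per, ggplot2::aes(x = .data$auc, fill = .data$curve)) +
    ggplot2::geom_histogram(bins = 20, alpha = 0.7, position = "identity") +
    ggplot2::geom_vline(xintercept = object$roc_auc, linetype = "dashed") +
    ggplot2::labs(x = "Per-subset AUC", y = "Subsets",
                  title = sprintf("Balanced-resampling AUC (%s)",
                                  object$mode)) +
    ggplot2::theme_minimal()
}

#' @rdname pdz-plots
#' @param records Interaction-record tibble (see [benchmark]).
#' @param threshold Binder-call score cutoff drawn as a vertical line.
#' @export
plot_score_distribution <- function(records, threshold = -2.11) {
  records <- check_records(records)
  ggplot2::ggplot(records,
                  ggplot2::aes(x = .data$score, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = threshold, linetype = "dashed") +
    ggplot2::labs(x = "Binding score (contact-potential units)",
                  y = "Density") +
    ggplot2::theme_minimal()
}
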
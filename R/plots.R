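# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a ROC curve
#'
#' @param object A [roc_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pepstack_roc <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate (1 - Sp)",
                  y = "True positive rate (Sn)") +
    ggplot2::theme_minimal()
}

#' Plot the metric distribution of repeated cross-validation
#'
#' One box per metric over the repeats, mirroring the usual stability
#' display of repeated k-fold protocols.
#'
#' @param object A [cv_pepstack()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.pepstack_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics[c("repeat_id", "Sn", "Sp", "Acc", "MCC", "AUC")],
    cols = -"repeat_id", names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$metric,
                                     y = .data$value)) +
    ggplot2::geom_boxplot(fill = "steelblue", alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "value",
                  title = sprintf("%d x %d-fold cross-validation",
                                  object$repeats, object$k)) +
    ggplot2::theme_minimal()
}

#' Plot per-class residue composition of a dataset summary
#'
#' @param object A [summarize_peptides()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.peptide_summary <- function(object, ...) {
  comp <- dplyr::mutate(
    object$composition,
    class = ifelse(.data$label == 1, "ACP", "non-ACP")
  )
  ggplot2::ggplot(comp, ggplot2::aes(x = .data$residue,
                                     y = .data$count,
                                     fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "amino acid", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
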
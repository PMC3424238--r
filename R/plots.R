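#' Plot per-antigen LOOCV AUCs
#'
#' Dot plot of the per-antigen AUC with the mean as a dashed line and the
#' 0.5 chance level dotted.
#'
#' @param object An `epitope_loocv` report.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.epitope_loocv <- function(object, ...) {
  d <- object$per_antigen[!is.na(object$per_antigen$auc), ]
  ggplot2::ggplot(d, ggplot2::aes(x = stats::reorder(.data$antigen_id, .data$auc),
                                  y = .data$auc)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = object$mean_auc, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dotted") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "per-antigen AUC",
                  title = sprintf("Antigen-level LOOCV (mean AUC %.3f)",
                                  object$mean_auc)) +
    ggplot2::theme_minimal()
}

#' Plot a per-residue score profile
#'
#' Line plot of the fused epitope score along each chain; residues labeled
#' as epitopes (when labels are present) are shaded.
#'
#' @param predictions A prediction tibble from [predict.epitope_model()].
#' @param threshold Optional horizontal threshold line.
#' @return A ggplot object.
#' @export
plot_score_profile <- function(predictions, threshold = NULL) {
  p <- ggplot2::ggplot(predictions,
                       ggplot2::aes(x = .data$position, y = .data$score)) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(antigen_id + chain_id ~ .) +
    ggplot2::labs(x = "residue position", y = "epitope score") +
    ggplot2::theme_minimal()
  if ("label" %in% names(predictions) && any(predictions$label == 1L, na.rm = TRUE)) {
    p <- p + ggplot2::geom_point(
      data = predictions[which(predictions$label == 1L), ],
      colour = "firebrick", size = 0.8
    )
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
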
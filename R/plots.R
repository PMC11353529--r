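#' Plot a threshold scan
#'
#' Connectivity-significance Z-scores (and observed sLCC, dashed) against
#' the coding perturbation threshold, one line per module kind.
#'
#' @param object A `beta_scan` tibble from [scan_beta()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.beta_scan <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$beta, y = .data$zscore,
                               colour = .data$kind)) +
    ggplot2::geom_hline(yintercept = c(0, 1.65), linetype = c(1, 3),
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(beta), y = "sLCC Z-score",
                  colour = NULL,
                  title = "Module connectivity significance") +
    ggplot2::theme_minimal()
}

#' Plot a disease similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot tile heatmap.
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  long <- tidyr::expand_grid(disease_a = object$labels,
                             disease_b = object$labels) |>
    dplyr::mutate(similarity = purrr::map2_dbl(
      .data$disease_a, .data$disease_b,
      function(a, b) object$values[a, b]))
  ggplot2::ggplot(long, ggplot2::aes(.data$disease_a, .data$disease_b,
                                     fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Jaccard") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot a drug-ranking ROC curve
#'
#' @param object A `proximity_ranking` from [rank_and_auc()].
#' @param ... Unused.
#' @return A ggplot ROC curve annotated with the AUC.
#' @export
autoplot.proximity_ranking <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = paste0("Drug proximity ranking: ",
                                 object$disease)) +
    ggplot2::theme_minimal()
}
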
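# ggplot2 methods for the main result types.

#' Plot cross-validation ROC curves
#'
#' One curve per fold plus the pooled curve, with the pooled AUROC in
#' the subtitle.
#'
#' @param object A `gkm_cv`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gkm_cv <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                           group = .data$fold)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(alpha = 0.4) +
    ggplot2::geom_step(data = object$pooled_roc,
                       ggplot2::aes(group = NULL), linewidth = 0.9) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = paste0("ROC, ", object$folds, "-fold cross-validation",
                     if (!is.null(object$class_label)) paste0(" (", object$class_label, ")")),
      subtitle = sprintf("pooled AUROC = %.3f", object$pooled_auroc)
    ) +
    ggplot2::theme_minimal()
}

#' Heat map of the cross-class score matrix
#'
#' Rows are peak sets, columns models, both in hierarchical-clustering
#' order; the diagonal should dominate when models are class-specific.
#'
#' @param object A `class_score_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.class_score_matrix <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$model, .data$peak_set,
                                             fill = .data$mean_score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b") +
    ggplot2::labs(x = "Model", y = "Peak set", fill = "Mean score",
                  title = "Cross-class scoring of uniform test sets") +
    ggplot2::theme_minimal()
}

#' Plot a saturation-mutagenesis VIP table
#'
#' Per-position summed VIP track with the individual per-allele scores
#' behind it.
#'
#' @param object A `vip_table` from [saturation_mutagenesis()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vip_table <- function(object, ...) {
  track <- summed_vip_track(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$pos, .data$vip)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.5) +
    ggplot2::geom_line(data = track, ggplot2::aes(.data$pos, .data$value),
                       colour = "#b2182b") +
    ggplot2::labs(x = "Position in region (bp)", y = "VIP score",
                  title = "In-silico saturation mutagenesis",
                  subtitle = "points: per-allele deltaSVM; line: per-base sum") +
    ggplot2::theme_minimal()
}

#' Plot motif-centered VIP profiles
#'
#' Mean VIP per offset around the motif (offset 0 = motif 5' end),
#' one panel per motif if several are present.
#'
#' @param profile Tibble from [motif_vip_profile()], optionally with a
#'   `model` column to colour by.
#' @return A ggplot.
#' @export
plot_motif_profile <- function(profile) {
  p <- ggplot2::ggplot(profile, ggplot2::aes(.data$offset, .data$mean_vip))
  p <- if ("model" %in% names(profile)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$model))
  } else p + ggplot2::geom_line()
  p +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::facet_wrap(ggplot2::vars(.data$motif_id)) +
    ggplot2::labs(x = "Offset from motif start (bp)", y = "Mean VIP",
                  title = "Average variant impact around motif occurrences") +
    ggplot2::theme_minimal()
}

#' Scatter plot of VIP versus MPRA expression change
#'
#' @param object A `vip_mpra` join from [join_vip_mpra()].
#' @param ... Unused.
#' @return A ggplot, faceted by cell class with per-class Pearson r.
#' @export
autoplot.vip_mpra <- function(object, ...) {
  lab <- object |>
    group_by(.data$cell_class) |>
    summarise(r = cor(.data$vip, .data$expression_change), .groups = "drop") |>
    mutate(label = sprintf("r = %.3f", .data$r))
  ggplot2::ggplot(object, ggplot2::aes(.data$vip, .data$expression_change)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5, colour = "#b2182b") +
    ggplot2::geom_text(data = lab, ggplot2::aes(label = .data$label),
                       x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
                       inherit.aes = FALSE) +
    ggplot2::facet_wrap(ggplot2::vars(.data$cell_class), scales = "free") +
    ggplot2::labs(x = "VIP score", y = "MPRA expression change",
                  title = "Predicted versus measured variant impact") +
    ggplot2::theme_minimal()
}
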
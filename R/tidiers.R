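# broom-style tidiers for fitted objects.

#' Tidy a gkm-SVM model's support vectors
#'
#' @param x A `gkm_model`.
#' @param ... Unused.
#' @return Tibble with one row per support vector (`seq`, `label`,
#'   `coef`).
#' @export
tidy.gkm_model <- function(x, ...) {
  select(x$support, "seq", "label", "coef")
}

#' One-row summary of a gkm-SVM model
#'
#' @param x A `gkm_model`.
#' @param ... Unused.
#' @return Tibble with class label, hyperparameters, support-vector
#'   count and training accuracy.
#' @export
glance.gkm_model <- function(x, ...) {
  tibble(class_label = x$class_label %||% NA_character_,
         l = x$params$l, k = x$params$k, d = x$params$d,
         C = x$params$C, both_strands = x$params$both_strands,
         n_support = nrow(x$support), bias = x$bias,
         train_accuracy = x$train_accuracy)
}

#' Per-fold cross-validation metrics
#'
#' @param x A `gkm_cv`.
#' @param ... Unused.
#' @return Tibble with `fold`, `auroc`, `auprc`.
#' @export
tidy.gkm_cv <- function(x, ...) x$metrics

#' One-row summary of a cross-validation run
#'
#' @param x A `gkm_cv`.
#' @param ... Unused.
#' @return Tibble with pooled AUROC/AUPRC and fold bookkeeping.
#' @export
glance.gkm_cv <- function(x, ...) {
  tibble(class_label = x$class_label %||% NA_character_,
         folds = x$folds, pooled_auroc = x$pooled_auroc,
         pooled_auprc = x$pooled_auprc,
         mean_fold_auroc = mean(x$metrics$auroc), seed = x$seed)
}

#' Long-form cross-class score matrix
#'
#' @param x A `class_score_matrix`.
#' @param ... Unused.
#' @return Tibble with `peak_set`, `model`, `mean_score`, ordered by
#'   the clustering.
#' @export
tidy.class_score_matrix <- function(x, ...) {
  M <- x$matrix[x$row_order, x$col_order, drop = FALSE]
  tibble(peak_set = rep(rownames(M), times = ncol(M)),
         model = rep(colnames(M), each = nrow(M)),
         mean_score = as.vector(M)) |>
    mutate(peak_set = factor(.data$peak_set, levels = rownames(M)),
           model = factor(.data$model, levels = colnames(M)))
}
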
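# Comparison of VIP predictions against massively parallel reporter
# assay (MPRA) expression changes per cell class.

#' Join VIP predictions with MPRA measurements
#'
#' Inner join on variant id and cell class, with the model-to-class
#' correspondence given explicitly.  Unmatched variant ids are
#' reported with a message.
#'
#' @param vip Tibble with `variant_id`, `model`, `vip` (long form; one
#'   row per variant per model).
#' @param mpra Tibble from [read_mpra_table()].
#' @param class_map Named character vector mapping model label to MPRA
#'   cell class; a model may map to several classes by repeating its
#'   name.
#' @return Joined tibble with `variant_id`, `model`, `cell_class`,
#'   `vip`, `expression_change` and, when present,
#'   `reference_expression`.
#' @export
join_vip_mpra <- function(vip, mpra, class_map) {
  if (is.null(names(class_map))) abort("class_map must be named (model -> cell class)")
  if (anyDuplicated(vip[c("variant_id", "model")]))
    abort("duplicate (variant_id, model) rows in VIP table")
  if (anyDuplicated(mpra[c("variant_id", "cell_class")]))
    abort("duplicate (variant_id, cell_class) rows in MPRA table")
  map_tbl <- tibble(model = names(class_map), cell_class = unname(class_map))
  missing_models <- setdiff(unique(vip$model), map_tbl$model)
  if (length(missing_models))
    inform(paste0("join_vip_mpra: models without a class mapping dropped: ",
                  paste(missing_models, collapse = ", ")))
  joined <- vip |>
    inner_join(map_tbl, by = "model", relationship = "many-to-many") |>
    inner_join(mpra, by = c("variant_id", "cell_class"))
  if (nrow(joined) == 0) abort("no overlap between VIP variants and MPRA records")
  misses <- setdiff(unique(vip$variant_id), unique(joined$variant_id))
  if (length(misses))
    inform(sprintf("join_vip_mpra: %d variant(s) without MPRA match", length(misses)))
  structure(joined, class = c("vip_mpra", class(joined)))
}

#' Pearson product-moment correlation
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero
#'   variance.
#' @return Scalar correlation.
#' @export
#' @examples
#' pearson_correlation(c(1, 2, 3), c(2, 4, 6))
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3) abort("need at least 3 pairs")
  if (sd(x) == 0 || sd(y) == 0) abort("zero variance")
  cor(x, y, method = "pearson")
}

#' Per-class correlation of VIP against MPRA expression change
#'
#' Classes with fewer than three variant pairs are excluded with a
#' message.  When reference expression is available its class mean is
#' reported alongside, supporting the observation that classes with
#' low reporter expression show weak correlation.
#'
#' @param joined Output of [join_vip_mpra()].
#' @param method `"pearson"` (reported throughout) or `"spearman"` for
#'   a robustness check.
#' @return Tibble with `cell_class`, `model`, `n`, `r` and, when
#'   available, `mean_reference_expression`.
#' @export
correlation_by_class <- function(joined, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  sizes <- count(joined, .data$cell_class)
  small <- sizes$cell_class[sizes$n < 3]
  if (length(small))
    inform(paste0("correlation_by_class: excluded classes with < 3 pairs: ",
                  paste(small, collapse = ", ")))
  out <- joined |>
    filter(!.data$cell_class %in% small) |>
    group_by(.data$cell_class, .data$model) |>
    summarise(
      n = dplyr::n(),
      r = if (sd(.data$expression_change) == 0 || sd(.data$vip) == 0)
        NA_real_ else cor(.data$vip, .data$expression_change, method = method),
      mean_reference_expression = if ("reference_expression" %in% names(joined))
        mean(.data$reference_expression) else NA_real_,
      .groups = "drop"
    )
  if (anyNA(out$r))
    inform("correlation_by_class: r is NA for classes with zero variance")
  out
}
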
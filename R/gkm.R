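# Gapped k-mer SVM engine.  The kernel between two sequences is the
# inner product of their gapped k-mer count vectors: every l-mer pair
# (u, v) with m mismatches contributes choose(l - m, k) shared gapped
# k-mers (0 when l - m < k or m exceeds the truncation d).  Training
# fits a soft-margin SVM on the normalized precomputed kernel matrix;
# prediction and the full l-mer weight table use per-pattern lookup
# tables built from the support vectors (exact for the untruncated
# kernel, d = l - k).

#' Gapped k-mer SVM hyperparameters
#'
#' @param l Word length (default 11; the vocabulary is all 4^l l-mers).
#' @param k Number of informative (ungapped) positions (default 7).
#' @param d Maximum mismatches counted between l-mer pairs; default
#'   `l - k` (untruncated, the exact gapped k-mer inner product).
#' @param both_strands Count the reverse-complement strand inside the
#'   kernel, making scores and k-mer weights strand-symmetric
#'   (default `TRUE`).
#' @param C Soft-margin cost (default 1).
#' @return A `gkm_params` list.
#' @export
gkm_params <- function(l = 11L, k = 7L, d = l - k, both_strands = TRUE, C = 1) {
  l <- as.integer(l); k <- as.integer(k); d <- as.integer(d)
  if (k < 1 || k > l || l > 16) abort("need 1 <= k <= l <= 16")
  if (d < 0 || d > l - k) abort("need 0 <= d <= l - k")
  structure(list(l = l, k = k, d = d, both_strands = isTRUE(both_strands), C = C),
            class = "gkm_params")
}

#' @export
print.gkm_params <- function(x, ...) {
  cat(sprintf("gkm-SVM parameters: l=%d k=%d d=%d both_strands=%s C=%g\n",
              x$l, x$k, x$d, x$both_strands, x$C))
  invisible(x)
}

#' Shared gapped k-mers between two l-mers with m mismatches
#'
#' Closed form for the pairwise kernel contribution:
#' `choose(l - m, k)` when `l - m >= k`, else 0.
#'
#' @param m Mismatch count(s).
#' @param l Word length.
#' @param k Informative positions.
#' @return Numeric vector of contributions.
#' @export
#' @examples
#' gkm_pair_contribution(0, 11, 7)  # choose(11, 7) = 330
gkm_pair_contribution <- function(m, l, k) {
  if (any(m < 0 | m > l)) abort("need 0 <= m <= l")
  vapply(m, cpp_pair_contribution, numeric(1), l = l, k = k)
}

#' Gapped k-mer kernel between two sequences
#'
#' @param x,y Sequences (A/C/G/T, length >= l).
#' @param params [gkm_params()].
#' @param raw Return the unnormalized kernel (integer-valued count of
#'   shared gapped k-mers over all l-mer pairs).  Default `FALSE`
#'   returns `K(x,y) / sqrt(K(x,x) K(y,y))`.
#' @return Scalar kernel value.
#' @export
gkm_kernel <- function(x, y, params = gkm_params(), raw = FALSE) {
  if (nchar(x) < params$l || nchar(y) < params$l)
    abort("sequences must be at least l bases long")
  v <- cpp_gkm_kernel_pair(x, y, params$l, params$k, params$d, params$both_strands)
  if (raw) return(v)
  sx <- cpp_gkm_kernel_pair(x, x, params$l, params$k, params$d, params$both_strands)
  sy <- cpp_gkm_kernel_pair(y, y, params$l, params$k, params$d, params$both_strands)
  v / sqrt(sx * sy)
}

#' Gapped k-mer kernel matrix over a set of sequences
#'
#' Uses a per-pattern bucket-count algorithm for the untruncated kernel
#' (`d = l - k`); truncated kernels fall back to the slower pairwise
#' diagonal-band computation.
#'
#' @param seqs Character vector (or tibble with `seq`).
#' @param params [gkm_params()].
#' @param raw Return raw counts instead of the normalized matrix.
#' @return Numeric n x n matrix.
#' @export
gkm_kernel_matrix <- function(seqs, params = gkm_params(), raw = FALSE) {
  seqs <- as_seqs(seqs)
  check_sequences(seqs, min_len = params$l)
  K <- if (params$d == params$l - params$k) {
    cpp_gkm_gram(seqs, params$l, params$k, params$both_strands)
  } else {
    n <- length(seqs)
    M <- matrix(0, n, n)
    for (i in seq_len(n)) for (j in i:n) {
      M[i, j] <- M[j, i] <- cpp_gkm_kernel_pair(seqs[i], seqs[j], params$l,
                                                params$k, params$d, params$both_strands)
    }
    M
  }
  if (raw) return(K)
  d <- sqrt(diag(K))
  K / tcrossprod(d)
}

# raw self kernels (normalization denominators) for arbitrary sequences
gkm_self_raw <- function(seqs, params) {
  cpp_gkm_self(seqs, params$l, params$k, params$d, params$both_strands)
}

# Fit kernlab's C-svc on a normalized kernel matrix and return dual
# coefficients oriented so the positive class scores high.  kernlab's
# internal +1/-1 coding is not exposed in input order, so the
# orientation is recovered from the fit's own fitted labels: the sign
# s with decision * s > 0 <=> fitted "pos".
fit_svm_on_kernel <- function(K, labels, C) {
  y <- factor(ifelse(labels > 0, "pos", "neg"), levels = c("pos", "neg"))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, type = "C-svc", C = C)
  sv <- kernlab::SVindex(fit)
  co <- as.numeric(kernlab::coef(fit)[[1]])
  bias <- -kernlab::b(fit)
  dec <- drop(K[, sv, drop = FALSE] %*% co) + bias
  fitted_pm <- ifelse(kernlab::fitted(fit) == "pos", 1, -1)
  if (sum(sign(dec) * fitted_pm) < 0) { co <- -co; bias <- -bias }
  list(sv = sv, coef = co, bias = bias)
}

#' Train a gapped k-mer SVM
#'
#' Fits a soft-margin SVM on the normalized gkm kernel matrix of
#' positive (accessible) versus negative (background) sequences.  A
#' small jitter (1e-8) is added to the kernel diagonal for numerical
#' stability.
#'
#' @param positives,negatives Character vectors of equal-width training
#'   sequences (or tibbles with a `seq` column).  Must be N-free.
#' @param params [gkm_params()].
#' @param class_label Optional cell-class label stored with the model.
#' @param gram Optional precomputed raw kernel matrix over
#'   `c(positives, negatives)` (as from `gkm_kernel_matrix(raw = TRUE)`),
#'   reused instead of recomputing.
#' @return A `gkm_model` object with the support sequences, dual
#'   coefficients, bias, training accuracy and a prediction lookup
#'   table.
#' @export
gkm_train <- function(positives, negatives, params = gkm_params(),
                      class_label = NULL, gram = NULL) {
  pos <- as_seqs(positives); neg <- as_seqs(negatives)
  if (length(pos) == 0 || length(neg) == 0)
    abort("both positive and negative sets must be non-empty")
  check_sequences(pos, params$l, "positive sequence")
  check_sequences(neg, params$l, "negative sequence")
  r <- length(pos) / length(neg)
  if (max(r, 1 / r) > 10) warn("label imbalance exceeds 10:1")
  seqs <- c(pos, neg)
  labels <- rep(c(1, -1), c(length(pos), length(neg)))
  if (is.null(gram)) gram <- gkm_kernel_matrix(seqs, params, raw = TRUE)
  dn <- sqrt(diag(gram))
  K <- gram / tcrossprod(dn)
  diag(K) <- diag(K) + 1e-8
  fit <- fit_svm_on_kernel(K, labels, params$C)
  support <- tibble(seq = seqs[fit$sv], label = labels[fit$sv], coef = fit$coef,
                    self_raw = diag(gram)[fit$sv])
  model <- structure(list(
    params = params, class_label = class_label,
    support = support, bias = fit$bias,
    score_table = NULL, train_accuracy = NA_real_
  ), class = "gkm_model")
  model <- build_score_table(model)
  dec <- predict(model, seqs)
  model$train_accuracy <- mean((dec > 0) == (labels > 0))
  model
}

# per-pattern lookup table from support sequences, with coefficients
# pre-divided by each SV's normalization denominator
build_score_table <- function(model) {
  p <- model$params
  if (p$d != p$l - p$k)
    abort("fast scoring tables require the untruncated kernel (d = l - k)")
  c_norm <- model$support$coef / sqrt(model$support$self_raw)
  model$score_table <- cpp_build_score_table(model$support$seq, c_norm,
                                             p$l, p$k, p$both_strands)
  model
}

#' @export
print.gkm_model <- function(x, ...) {
  cat(sprintf("gkm-SVM model%s: l=%d k=%d, %d support vectors, training accuracy %.3f\n",
              if (is.null(x$class_label)) "" else paste0(" [", x$class_label, "]"),
              x$params$l, x$params$k, nrow(x$support), x$train_accuracy))
  invisible(x)
}

#' Decision values of a gkm-SVM for new sequences
#'
#' @param object A `gkm_model`.
#' @param newdata Character vector of sequences (or tibble with `seq`).
#' @param na_action For sequences containing N: `"error"` (default) or
#'   `"na"` to return NA with a message.
#' @param ... Unused.
#' @return Numeric decision values; higher means more accessible-like
#'   for the model's class.
#' @export
predict.gkm_model <- function(object, newdata, na_action = c("error", "na"), ...) {
  na_action <- match.arg(na_action)
  seqs <- as_seqs(newdata)
  p <- object$params
  bad <- is.na(seqs) | nchar(seqs) < p$l | stringr::str_detect(seqs, "[^ACGTacgt]")
  if (any(bad)) {
    if (na_action == "error") abort(sprintf("%d sequence(s) unscorable (N or shorter than l)", sum(bad)))
    inform(sprintf("predict: skipping %d unscorable sequence(s)", sum(bad)))
  }
  out <- rep(NA_real_, length(seqs))
  ok <- which(!bad)
  if (length(ok)) {
    s <- cpp_score_with_table(object$score_table, seqs[ok], p$l, p$k)
    self <- gkm_self_raw(seqs[ok], p)
    out[ok] <- s / sqrt(self) + object$bias
  }
  out
}

#' @rdname predict.gkm_model
#' @param model A `gkm_model`.
#' @param seqs Sequences to score.
#' @export
predict_score <- function(model, seqs, ...) predict(model, seqs, ...)

#' Score every l-mer of the vocabulary with a trained model
#'
#' The weight of an l-mer is its SVM decision value minus the bias
#' (the centered, summable contribution used by deltaSVM scoring).
#' With `both_strands = TRUE` the table is reverse-complement
#' symmetric.
#'
#' @param model A `gkm_model`.
#' @return A `kmer_weights` object: the 4^l weight vector indexed by
#'   l-mer code, with word length and strand mode attached.
#' @export
extract_kmer_weights <- function(model) {
  p <- model$params
  if (p$l > 16) abort("weight table infeasible for l > 16")
  w <- cpp_weight_table(model$score_table, p$l, p$k, p$both_strands)
  kmer_weights(w, l = p$l, both_strands = p$both_strands,
               class_label = model$class_label)
}

#' Construct a k-mer weight table
#'
#' @param weights Numeric vector of length 4^l indexed by l-mer code
#'   (lexicographic: AAA.., AAC.., ...), or a named vector of all 4^l
#'   k-mer strings.
#' @param l Word length.
#' @param both_strands Whether weights are strand-symmetric.
#' @param class_label Optional model label.
#' @return A `kmer_weights` object.
#' @export
kmer_weights <- function(weights, l, both_strands = TRUE, class_label = NULL) {
  l <- as.integer(l)
  if (length(weights) != 4^l) abort("weights must have length 4^l")
  if (!is.null(names(weights))) {
    codes <- cpp_kmers_to_codes(names(weights), l)
    weights <- weights[order(codes)]
    names(weights) <- NULL
  }
  structure(list(l = l, weights = as.numeric(weights),
                 both_strands = both_strands, class_label = class_label),
            class = "kmer_weights")
}

#' @export
print.kmer_weights <- function(x, ...) {
  cat(sprintf("k-mer weight table%s: %d %d-mers, range [%.4g, %.4g]\n",
              if (is.null(x$class_label)) "" else paste0(" [", x$class_label, "]"),
              length(x$weights), x$l, min(x$weights), max(x$weights)))
  invisible(x)
}

#' @export
as_tibble.kmer_weights <- function(x, ...) {
  tibble(kmer = cpp_codes_to_kmers(seq_along(x$weights) - 1L, x$l),
         weight = x$weights)
}

#' Look up weights for specific k-mers
#'
#' @param weights A `kmer_weights` object.
#' @param kmers Character vector of l-mers.
#' @return Numeric weights.
#' @export
kmer_weight <- function(weights, kmers) {
  weights$weights[cpp_kmers_to_codes(kmers, weights$l) + 1L]
}

#' ROC curve and area by the trapezoidal rule
#'
#' @param scores Numeric decision values.
#' @param labels Logical or +1/-1 labels (TRUE/+1 = positive).
#' @return List with `curve` (tibble `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  labels <- labels > 0
  if (!any(labels) || all(labels)) abort("need both classes for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # one point per distinct threshold
  tpr <- c(0, tp[keep] / sum(y))
  fpr <- c(0, fp[keep] / sum(!y))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tpr[-1]) / 2)
  list(curve = tibble(fpr = fpr, tpr = tpr), auc = auc)
}

#' Precision-recall curve and area
#'
#' @inheritParams roc_curve
#' @return List with `curve` (tibble `recall`, `precision`) and `auc`.
#' @export
pr_curve <- function(scores, labels) {
  labels <- labels > 0
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  tp <- cumsum(y); fp <- cumsum(!y)
  keep <- c(s[-1] != s[-length(s)], TRUE)
  recall <- tp[keep] / sum(y)
  precision <- tp[keep] / (tp[keep] + fp[keep])
  recall <- c(0, recall); precision <- c(precision[1], precision)
  auc <- sum(diff(recall) * (head(precision, -1) + precision[-1]) / 2)
  list(curve = tibble(recall = recall, precision = precision), auc = auc)
}

#' Five-fold cross-validation of a gkm-SVM
#'
#' Stratified, seeded fold assignment; one SVM per fold trained on the
#' remaining folds' submatrix of a single precomputed kernel matrix;
#' out-of-fold decision values pooled for the headline AUROC.
#'
#' @inheritParams gkm_train
#' @param folds Number of folds (default 5).
#' @param seed Integer seed for fold assignment.
#' @return A `gkm_cv` object: per-fold ROC/PR curves, per-fold and
#'   pooled AUROC/AUPRC, and the pooled decision values.
#' @export
gkm_cv <- function(positives, negatives, params = gkm_params(), folds = 5L,
                   seed = 1L, class_label = NULL, gram = NULL) {
  if (folds < 2) abort("need at least 2 folds")
  pos <- as_seqs(positives); neg <- as_seqs(negatives)
  if (length(pos) < folds || length(neg) < folds)
    abort("need at least `folds` examples per class")
  seqs <- c(pos, neg)
  labels <- rep(c(1, -1), c(length(pos), length(neg)))
  if (is.null(gram)) gram <- gkm_kernel_matrix(seqs, params, raw = TRUE)
  dn <- sqrt(diag(gram))
  K <- gram / tcrossprod(dn)
  diag(K) <- diag(K) + 1e-8
  fold_id <- integer(length(seqs))
  with_seed(seed, {
    fold_id[labels > 0] <- sample(rep_len(seq_len(folds), length(pos)))
    fold_id[labels < 0] <- sample(rep_len(seq_len(folds), length(neg)))
  })
  scores <- purrr::map_dfr(seq_len(folds), function(f) {
    tr <- which(fold_id != f); te <- which(fold_id == f)
    fit <- fit_svm_on_kernel(K[tr, tr, drop = FALSE], labels[tr], params$C)
    dec <- drop(K[te, tr[fit$sv], drop = FALSE] %*% fit$coef) + fit$bias
    tibble(fold = f, index = te, label = labels[te], decision = dec)
  })
  per_fold <- scores |> group_by(.data$fold) |> group_modify(function(df, key) {
    r <- roc_curve(df$decision, df$label); p <- pr_curve(df$decision, df$label)
    tibble(auroc = r$auc, auprc = p$auc)
  }) |> ungroup()
  roc_curves <- scores |> group_by(.data$fold) |> group_modify(function(df, key)
    roc_curve(df$decision, df$label)$curve) |> ungroup()
  pooled_roc <- roc_curve(scores$decision, scores$label)
  pooled_pr <- pr_curve(scores$decision, scores$label)
  structure(list(
    scores = scores, roc = roc_curves, metrics = per_fold,
    pooled_auroc = pooled_roc$auc, pooled_auprc = pooled_pr$auc,
    pooled_roc = pooled_roc$curve, folds = folds, seed = seed,
    params = params, class_label = class_label
  ), class = "gkm_cv")
}

#' @export
print.gkm_cv <- function(x, ...) {
  cat(sprintf("gkm-SVM %d-fold CV%s: pooled AUROC %.4f, AUPRC %.4f\n",
              x$folds,
              if (is.null(x$class_label)) "" else paste0(" [", x$class_label, "]"),
              x$pooled_auroc, x$pooled_auprc))
  invisible(x)
}

#' Cross-class score matrix with hierarchical clustering
#'
#' Scores every class's uniform test set with every model: entry (i, j)
#' is the mean decision value of model j over peak set i.  Rows and
#' columns are ordered by average-linkage hierarchical clustering on
#' correlation distance (1 - r), so related classes cluster together
#' and each model should recognize its own class best.
#'
#' @param models Named list of `gkm_model` objects.
#' @param testsets Tibble with `class` and `seq` columns (the uniform
#'   test regions of each class).
#' @return A `class_score_matrix` object with the mean-score matrix,
#'   clustering orders and dendrograms.
#' @export
cross_class_score_matrix <- function(models, testsets) {
  if (is.null(names(models)))
    names(models) <- purrr::map_chr(models, function(m) m$class_label %||% "model")
  classes <- unique(testsets$class)
  if (length(classes) == 0 || nrow(testsets) == 0) abort("empty test set")
  by_class <- split(testsets$seq, testsets$class)[classes]
  if (any(lengths(by_class) == 0)) abort("empty test set for a class")
  M <- vapply(models, function(m)
    vapply(by_class, function(s) mean(predict(m, s)), numeric(1)),
    numeric(length(classes)))
  M <- matrix(M, nrow = length(classes), ncol = length(models),
              dimnames = list(classes, names(models)))
  cluster_order <- function(mat) {
    if (nrow(mat) < 3) return(list(order = seq_len(nrow(mat)), hclust = NULL))
    cc <- suppressWarnings(cor(t(mat)))
    cc[!is.finite(cc)] <- 0
    hc <- hclust(as.dist(1 - cc), method = "average")
    list(order = hc$order, hclust = hc)
  }
  ro <- cluster_order(M); co <- cluster_order(t(M))
  structure(list(matrix = M, row_order = ro$order, col_order = co$order,
                 row_hclust = ro$hclust, col_hclust = co$hclust),
            class = "class_score_matrix")
}

#' @export
print.class_score_matrix <- function(x, ...) {
  cat("cross-class mean score matrix (rows = peak sets, cols = models):\n")
  print(round(x$matrix[x$row_order, x$col_order, drop = FALSE], 4))
  invisible(x)
}

#' Serialize a gkm-SVM model to JSON
#'
#' @param model A `gkm_model`.
#' @param path Output path.
#' @export
write_gkm_model <- function(model, path) {
  obj <- list(
    params = unclass(model$params), class_label = model$class_label,
    bias = model$bias, train_accuracy = model$train_accuracy,
    support = as.list(model$support)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a gkm-SVM model from JSON
#'
#' @param path Path written by [write_gkm_model()].
#' @return A `gkm_model` with its scoring table rebuilt.
#' @export
read_gkm_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- do.call(gkm_params, obj$params[c("l", "k", "d", "both_strands", "C")])
  model <- structure(list(
    params = params, class_label = obj$class_label,
    support = as_tibble(obj$support), bias = obj$bias,
    score_table = NULL, train_accuracy = obj$train_accuracy
  ), class = "gkm_model")
  build_score_table(model)
}

#' Write a k-mer weight table as 2-column TSV
#'
#' @param weights A `kmer_weights` object.
#' @param path Output path (use a `.gz` suffix to compress).
#' @export
write_kmer_weights <- function(weights, path) {
  readr::write_tsv(as_tibble(weights), path)
  invisible(path)
}
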
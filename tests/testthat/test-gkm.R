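test_that("pairwise contribution follows the closed form", {
  expect_equal(gkm_pair_contribution(0, 11, 7), 330)
  expect_equal(gkm_pair_contribution(4, 11, 7), 1)
  expect_equal(gkm_pair_contribution(5, 11, 7), 0)
  expect_equal(gkm_pair_contribution(0:4, 4, 3), c(4, 1, 0, 0, 0))
  expect_error(gkm_pair_contribution(-1, 4, 3))
})

test_that("kernel matches hand-derived values on tiny sequences", {
  p <- gkm_params(l = 4, k = 3, both_strands = FALSE)
  # self: two l-mers, cross pairs fully mismatched
  expect_equal(gkm_kernel("ACGTA", "ACGTA", p, raw = TRUE), 8)
  expect_equal(gkm_kernel("AAAA", "AAAT", p, raw = TRUE), 1)
  expect_equal(gkm_kernel("AAAA", "AAAT", p), 0.25)
  expect_equal(gkm_kernel("ACGTACGT", "ACGTACGT", p), 1.0)
  expect_error(gkm_kernel("ACG", "ACGT", p), "at least")
})

test_that("raw kernel equals the explicit gapped k-mer inner product", {
  withr::with_seed(5, {
    cases <- tidyr::crossing(l = 4:6, k = 2:4, both = c(FALSE, TRUE)) |>
      dplyr::filter(k < l)
    n_checked <- 0L
    for (i in seq_len(nrow(cases))) {
      l <- cases$l[i]; k <- cases$k[i]; both <- cases$both[i]
      p <- gkm_params(l = l, k = k, both_strands = both)
      for (rep in 1:9) {
        x <- random_dna(1, sample(l:30, 1))
        y <- random_dna(1, sample(l:30, 1))
        expect_identical(gkm_kernel(x, y, p, raw = TRUE),
                         oracle_kernel(x, y, l, k, both))
        n_checked <- n_checked + 1L
      }
    }
    expect_gte(n_checked, 100L)
  })
})

test_that("truncated kernel matches a direct mismatch-capped enumeration", {
  withr::with_seed(6, {
    for (rep in 1:20) {
      x <- random_dna(1, 15); y <- random_dna(1, 15)
      d <- sample(0:2, 1)
      p <- gkm_params(l = 5, k = 3, d = d, both_strands = rep %% 2 == 0)
      expect_equal(gkm_kernel(x, y, p, raw = TRUE),
                   oracle_kernel_truncated(x, y, 5, 3, d, p$both_strands))
    }
  })
})

test_that("kernel is symmetric, bounded, and the Gram matrix agrees pairwise", {
  withr::with_seed(7, {
    seqs <- random_dna(8, 25)
    p <- gkm_params(l = 5, k = 3)
    K <- gkm_kernel_matrix(seqs, p)
    expect_equal(K, t(K))
    expect_true(all(abs(K) <= 1 + 1e-12))
    expect_equal(diag(K), rep(1, 8))
    i <- 2; j <- 7
    expect_equal(K[i, j], gkm_kernel(seqs[i], seqs[j], p))
  })
})

test_that("training separates a planted exact motif perfectly", {
  toy <- planted_toy()
  p <- gkm_params(l = 6, k = 4)
  m <- gkm_train(toy$pos, toy$neg, p, class_label = "toy")
  expect_s3_class(m, "gkm_model")
  expect_equal(m$train_accuracy, 1.0)

  # margin property: positively-weighted support vectors score positive
  sv_pos <- m$support$seq[m$support$coef > 0]
  expect_true(all(predict(m, sv_pos) > 0))

  # planting the motif into background raises the score (paired check)
  withr::with_seed(2, bg <- random_dna(20, 30))
  planted <- vapply(bg, function(s)
    paste0(substr(s, 1, 10), "GATTACA", substr(s, 18, 30)), "")
  expect_true(all(predict(m, planted) > predict(m, bg)))

  # reverse-complement invariance under both-strand counting
  seqs <- c(toy$pos[1:5], bg[1:5])
  expect_equal(predict(m, seqs),
               predict(m, reverse_complement(seqs)), tolerance = 1e-9)

  expect_error(gkm_train(toy$pos, character(0), p), "non-empty")
})

test_that("identical positive and negative sets give chance-level decisions", {
  withr::with_seed(3, seqs <- random_dna(12, 20))
  p <- gkm_params(l = 5, k = 3)
  m <- suppressWarnings(gkm_train(seqs, seqs, p))
  expect_lt(max(abs(predict(m, seqs))), 0.5)
  expect_lt(abs(m$train_accuracy - 0.5), 0.26)
})

test_that("prediction matches kernlab's own decision values", {
  toy <- planted_toy(n = 15, seed = 21)
  p <- gkm_params(l = 5, k = 3)
  seqs <- c(toy$pos, toy$neg)
  labels <- rep(c(1, -1), each = 15)
  gram <- gkm_kernel_matrix(seqs, p, raw = TRUE)
  K <- gram / tcrossprod(sqrt(diag(gram)))
  fit <- kernlab::ksvm(kernlab::as.kernelMatrix(K + diag(1e-8, nrow(K))),
                       factor(ifelse(labels > 0, "pos", "neg"), c("pos", "neg")),
                       type = "C-svc", C = 1)
  ref <- drop(kernlab::predict(
    fit, kernlab::as.kernelMatrix(K[, kernlab::SVindex(fit), drop = FALSE]),
    type = "decision"))
  m <- gkm_train(toy$pos, toy$neg, p, gram = gram)
  mine <- predict(m, seqs)
  # same decision boundary up to kernlab's internal sign convention
  expect_equal(abs(cor(mine, ref)), 1, tolerance = 1e-6)
  expect_true(all(sign(mine[1:15]) == 1) || m$train_accuracy < 1)
})

test_that("l-mer weight table is complete, RC-symmetric, and tied to the decision", {
  toy <- planted_toy(n = 12, len = 20, motif = "GATTACA", seed = 13)
  p <- gkm_params(l = 3, k = 2)
  m <- gkm_train(toy$pos, toy$neg, p)
  w <- extract_kmer_weights(m)
  expect_length(w$weights, 64L)

  tab <- tibble::as_tibble(w)
  expect_equal(nrow(tab), 64L)
  # top-weight 3-mer lies inside the planted motif
  best <- tab$kmer[which.max(tab$weight)]
  expect_true(grepl(best, "GATTACA") || grepl(best, reverse_complement("GATTACA")))

  # RC symmetry of the table
  expect_equal(kmer_weight(w, tab$kmer),
               kmer_weight(w, reverse_complement(tab$kmer)), tolerance = 1e-9)

  # weight = decision value of the bare l-mer minus the bias
  some <- c("GAT", "ACA", "TTT", "CGC")
  expect_equal(kmer_weight(w, some), predict(m, some) - m$bias, tolerance = 1e-9)
})

test_that("ROC/AUROC follow the rank statistic and match pROC", {
  r <- roc_curve(c(0.9, 0.8, 0.1, 0.2), c(1, 1, -1, -1))
  expect_equal(r$auc, 1.0)
  r2 <- roc_curve(c(0.9, 0.1, 0.8, 0.2), c(1, 1, -1, -1))
  expect_equal(r2$auc, 0.5)

  withr::with_seed(8, {
    scores <- rnorm(60)
    labels <- rep(c(1, -1), 30)
    expect_equal(roc_curve(scores, labels)$auc,
                 as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                                direction = "<"))))
  })
})

test_that("cross-validation is stratified, seeded and sane under no signal", {
  toy <- planted_toy(n = 40, seed = 31)
  p <- gkm_params(l = 6, k = 4)
  cv <- gkm_cv(toy$pos, toy$neg, p, folds = 5, seed = 2)
  # separable within every fold; pooling mixes fold decision scales
  expect_true(all(cv$metrics$auroc == 1.0))
  expect_gt(cv$pooled_auroc, 0.99)
  expect_equal(sort(unique(cv$scores$fold)), 1:5)
  # folds partition the data
  expect_equal(sort(cv$scores$index), seq_len(80))

  withr::with_seed(9, {
    null_seqs <- random_dna(200, 20)
    cvn <- gkm_cv(null_seqs[1:100], null_seqs[101:200],
                  gkm_params(l = 5, k = 3), folds = 5, seed = 2)
    expect_gte(cvn$pooled_auroc, 0.4)
    expect_lte(cvn$pooled_auroc, 0.6)
  })
  expect_error(gkm_cv(toy$pos, toy$neg, p, folds = 1), "folds")
})

test_that("cross-class scoring handles the degenerate single-model case", {
  toy <- planted_toy(n = 12, seed = 41)
  m <- gkm_train(toy$pos, toy$neg, gkm_params(l = 5, k = 3), class_label = "A")
  ts <- tibble::tibble(class = "A", seq = toy$pos[1:5])
  mat <- cross_class_score_matrix(list(A = m), ts)
  expect_equal(dim(mat$matrix), c(1L, 1L))
  expect_null(mat$row_hclust)
  expect_error(cross_class_score_matrix(list(A = m), ts[0, ]), "empty")
})

test_that("models serialize to JSON and score identically after reload", {
  toy <- planted_toy(n = 10, seed = 51)
  m <- gkm_train(toy$pos, toy$neg, gkm_params(l = 5, k = 3), class_label = "A")
  f <- withr::local_tempfile(fileext = ".json")
  write_gkm_model(m, f)
  m2 <- read_gkm_model(f)
  probe <- c(toy$pos[1:3], toy$neg[1:3])
  expect_equal(predict(m2, probe), predict(m, probe), tolerance = 1e-9)
  expect_equal(m2$class_label, "A")
})
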
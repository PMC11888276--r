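# Shared fixtures and independent oracles.  Heavy objects are built
# lazily once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

random_dna <- function(n, len, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, TRUE, prob = p), collapse = ""), "")
}

# ---- independent gapped k-mer oracle ------------------------------------
# Explicit feature vectors: one feature per (position pattern, projected
# letters); the kernel is their inner product.  Used to validate the
# C++ kernel; shares no code with it.

oracle_features <- function(seq, l, k) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pats <- utils::combn(l, k)
  feats <- character(0)
  for (start in seq_len(n - l + 1)) {
    word <- chars[start:(start + l - 1)]
    for (j in seq_len(ncol(pats))) {
      feats <- c(feats, paste0(paste(pats[, j], collapse = ","), ":",
                               paste(word[pats[, j]], collapse = "")))
    }
  }
  table(feats)
}

oracle_revcomp <- function(seq) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", seq), "")[[1]]), collapse = "")
}

oracle_kernel <- function(x, y, l, k, both_strands = FALSE) {
  fx <- oracle_features(x, l, k)
  fy <- oracle_features(y, l, k)
  dot <- function(a, b) {
    shared <- intersect(names(a), names(b))
    sum(as.numeric(a[shared]) * as.numeric(b[shared]))
  }
  v <- dot(fx, fy)
  if (both_strands) v <- v + dot(fx, oracle_features(oracle_revcomp(y), l, k))
  v
}

# truncated-kernel oracle: direct double loop over l-mer pairs with the
# closed-form contribution, restricted to hamming <= d
oracle_kernel_truncated <- function(x, y, l, k, d, both_strands = FALSE) {
  lmers <- function(s) {
    chars <- strsplit(s, "")[[1]]
    vapply(seq_len(nchar(s) - l + 1), function(i)
      paste(chars[i:(i + l - 1)], collapse = ""), "")
  }
  contrib <- function(u, v) {
    m <- sum(strsplit(u, "")[[1]] != strsplit(v, "")[[1]])
    if (m <= d && l - m >= k) choose(l - m, k) else 0
  }
  total <- sum(outer(lmers(x), lmers(y), Vectorize(contrib)))
  if (both_strands)
    total <- total + sum(outer(lmers(x), lmers(oracle_revcomp(y)), Vectorize(contrib)))
  total
}

# ---- small planted-motif study (fast; used across test files) ----------

small_spec <- function() {
  synthetic_spec(n_classes = 3, peaks_per_class = 60, region_width = 101,
                 genome_length = 3e5, motif_length = 8, seed = 42)
}

get_small_sim <- function() cached("small_sim", function() {
  simulate_genome_and_peaks(small_spec())
})

small_params <- function() gkm_params(l = 6, k = 4)

get_small_run <- function() cached("small_run", function() {
  sim <- get_small_sim()
  cfg <- crevip_config(genome = sim$genome, peaks = sim$peaks,
                       motifs = sim$motifs, params = small_params(),
                       flank = 50, top_n = 1000, seed = 42,
                       n_saturation_regions = 5, flank_context = 50)
  prep <- suppressMessages(run_prepare(cfg))
  trained <- suppressMessages(run_train_and_evaluate(cfg, prep))
  list(cfg = cfg, sim = sim, prep = prep, trained = trained)
})

# toy linearly separable training problem: planted exact motif vs
# background scrubbed of the motif and of its long partial matches (so
# no negative shares an l-mer with the motif core at l <= 6)
planted_toy <- function(n = 20, len = 30, motif = "GATTACA", seed = 11) {
  scrub <- function(seqs) {
    pats <- unique(c(motif, substring(motif, 1, nchar(motif) - 1),
                     substring(motif, 2, nchar(motif))))
    for (p in sort(pats, decreasing = TRUE)) {
      repl <- paste(rep_len(c("C", "A"), nchar(p)), collapse = "")
      seqs <- gsub(p, repl, seqs, fixed = TRUE)
      seqs <- gsub(crevip::reverse_complement(p),
                   crevip::reverse_complement(repl), seqs, fixed = TRUE)
    }
    seqs
  }
  withr::with_seed(seed, {
    neg <- scrub(random_dna(n, len))
    pos <- vapply(scrub(random_dna(n, len)), function(s) {
      at <- sample.int(len - nchar(motif) + 1, 1)
      paste0(substr(s, 1, at - 1), motif, substr(s, at + nchar(motif), len))
    }, "")
    list(pos = unname(pos), neg = neg)
  })
}

expect_tibble <- function(x) testthat::expect_s3_class(x, "tbl_df")
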
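random_weights <- function(l, seed = 1, symmetric = FALSE) {
  withr::with_seed(seed, w <- rnorm(4^l))
  if (symmetric) {
    rc <- crevip:::cpp_revcomp_codes(seq_len(4^l) - 1L, as.integer(l))
    w <- (w + w[rc + 1L]) / 2
  }
  kmer_weights(w, l = l, both_strands = symmetric)
}

test_that("additive scoring sums sliding l-mer weights", {
  zero <- kmer_weights(rep(0, 4^3), l = 3)
  expect_equal(score_sequence_additive(zero, random_dna(1, 40)), 0)

  # l = 2 toy: only AA weighs 1; "AAA" has two AA windows
  v <- rep(0, 16); v[1] <- 1
  kw <- kmer_weights(v, l = 2, both_strands = FALSE)
  expect_equal(score_sequence_additive(kw, "AAA"), 2)
  expect_error(score_sequence_additive(kw, "A"), "shorter")
})

test_that("windowed SNV deltaSVM equals the full additive rescore", {
  w <- random_weights(5, seed = 2)
  withr::with_seed(3, {
    for (i in 1:25) {
      seq <- random_dna(1, 60)
      pos <- sample(0:59, 1)
      ref <- substr(seq, pos + 1, pos + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      alt_seq <- apply_variant(seq, pos, ref, alt)
      expect_equal(delta_svm_snv(w, seq, pos, alt),
                   score_sequence_additive(w, alt_seq) -
                     score_sequence_additive(w, seq),
                   tolerance = 1e-9)
    }
  })
  expect_warning(z <- delta_svm_snv(w, "ACGTACGTAC", 2, "G"), "alt equals ref")
  expect_equal(z, 0)
})

test_that("VIP depends only on sequence within l-1 bp of the edit", {
  w <- random_weights(5, seed = 4)
  withr::with_seed(5, {
    core <- random_dna(1, 9)  # 2(l-1) + 1
    for (i in 1:5) {
      left <- random_dna(1, 30); right <- random_dna(1, 30)
      seq <- paste0(left, core, right)
      v <- delta_svm_snv(w, seq, 34, "A")
      if (i == 1) first <- v else expect_equal(v, first, tolerance = 1e-9)
    }
  })
})

test_that("VIP is strand-consistent for symmetric weight tables", {
  w <- random_weights(5, seed = 6, symmetric = TRUE)
  withr::with_seed(7, {
    for (i in 1:10) {
      seq <- random_dna(1, 40)
      pos <- sample(10:30, 1)
      ref <- substr(seq, pos + 1, pos + 1)
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      fwd <- delta_svm_snv(w, seq, pos, alt)
      rc_seq <- reverse_complement(seq)
      rc_pos <- nchar(seq) - 1 - pos
      rc_alt <- chartr("ACGT", "TGCA", alt)
      expect_equal(delta_svm_snv(w, rc_seq, rc_pos, rc_alt), fwd, tolerance = 1e-9)
    }
  })
})

test_that("saturation mutagenesis yields 3 entries per N-free position", {
  w <- random_weights(5, seed = 8)
  seq <- random_dna(1, 301)
  vt <- saturation_mutagenesis(w, seq)
  expect_equal(nrow(vt), 903L)
  expect_equal(as.integer(table(vt$pos)), rep(3L, 301))

  # 5 bp region with l = 5: a single window scores every variant
  short <- saturation_mutagenesis(w, "ACGTA")
  expect_equal(nrow(short), 15L)

  flat <- kmer_weights(rep(2, 4^5), l = 5)
  vflat <- saturation_mutagenesis(flat, seq)
  expect_true(all(vflat$vip == 0))

  withN <- paste0(substr(seq, 1, 150), "N", substr(seq, 152, 301))
  expect_message(vn <- saturation_mutagenesis(w, withN), "skipped")
  expect_lt(nrow(vn), 903L)
})

test_that("summed track adds the three alternate VIPs per position", {
  vt <- tibble::tibble(pos = c(0L, 0L, 0L, 1L, 1L, 1L),
                       ref = "A", alt = c("C", "G", "T", "C", "G", "T"),
                       vip = c(-1, -2, 0, 1, 1, 1))
  tr <- summed_vip_track(vt)
  expect_equal(tr$value, c(-3, 3))
})

test_that("indel scoring rescans whole constructs", {
  w <- random_weights(5, seed = 9)
  seq <- random_dna(1, 50)
  expect_equal(delta_svm_indel(w, seq, seq), 0)
  del <- apply_variant(seq, 10, substr(seq, 11, 18), "")
  expect_equal(delta_svm_indel(w, seq, del),
               score_sequence_additive(w, del) - score_sequence_additive(w, seq),
               tolerance = 1e-12)
})

test_that("motif occurrence scanning recovers planted loci and deduplicates palindromes", {
  genome <- c(chr1 = paste0(strrep("A", 40), "ACGTTGCA", strrep("A", 40)))
  pfm <- local({
    idx <- match(strsplit("ACGTTGCA", "")[[1]], c("A", "C", "G", "T"))
    m <- vapply(idx, function(i) { p <- rep(1, 4); p[i] <- 97; p }, numeric(4))
    rownames(m) <- c("A", "C", "G", "T"); m
  })
  motifs <- tibble::tibble(motif_id = "m1", motif_name = "M", pfm = list(pfm))
  regions <- tibble::tibble(chrom = "chr1", start = 0L, end = 88L)
  occ <- scan_motif_occurrences(regions, genome, motifs, threshold_frac = 0.9)
  expect_equal(nrow(occ), 1L)
  expect_equal(occ$start, 40L)
  expect_equal(occ$end, 48L)

  # palindromic consensus: both strands hit, collapsed to forward
  pal_genome <- c(chr1 = paste0(strrep("C", 30), "ACGTACGT", strrep("C", 30)))
  pal_pfm <- local({
    idx <- match(strsplit("ACGTACGT", "")[[1]], c("A", "C", "G", "T"))
    m <- vapply(idx, function(i) { p <- rep(1, 4); p[i] <- 97; p }, numeric(4))
    rownames(m) <- c("A", "C", "G", "T"); m
  })
  pal <- tibble::tibble(motif_id = "p1", motif_name = "P", pfm = list(pal_pfm))
  pocc <- scan_motif_occurrences(tibble::tibble(chrom = "chr1", start = 0L, end = 68L),
                                 pal_genome, pal, threshold_frac = 0.9)
  expect_equal(nrow(pocc), 1L)
  expect_equal(pocc$strand, "+")
})

test_that("motif profiles average VIP in motif orientation", {
  # uniform VIP = -1 everywhere gives a constantly -1 profile
  vt <- tibble::tibble(chrom = "chr1", genome_pos = rep(0:99, each = 3),
                       pos = rep(0:99, each = 3), ref = "A",
                       alt = rep(c("C", "G", "T"), 100), vip = -1)
  occ <- tibble::tibble(motif_id = "m1", chrom = "chr1", start = 50L, end = 58L,
                        strand = "+", score = 1)
  prof <- motif_vip_profile(list(vt), occ, window = 10)
  expect_equal(nrow(prof), 8L + 2L * 10L)
  expect_true(all(prof$mean_vip == -1))
  expect_equal(range(prof$offset), c(-10L, 17L))

  # minus-strand occurrences flip into motif orientation
  vt2 <- dplyr::mutate(vt, vip = rep(seq(-99.5, -0.5), each = 3) / 100)
  occm <- dplyr::mutate(occ, strand = "-")
  pm <- motif_vip_profile(list(vt2), occm, window = 2)
  pp <- motif_vip_profile(list(vt2), occ, window = 2)
  expect_equal(pm$mean_vip, rev(pp$mean_vip), tolerance = 1e-9)

  expect_error(motif_vip_profile(list(vt), occ[0, ]), "no motif occurrences")
})

test_that("variant tables score per model with locality and ref checks", {
  w1 <- random_weights(5, seed = 10)
  w2 <- random_weights(5, seed = 11)
  withr::with_seed(12, genome <- c(chr1 = random_dna(1, 400)))
  variants <- tibble::tibble(id = c("v1", "v2"), chrom = "chr1",
                             pos = c(100L, 200L),
                             ref = substring(genome, c(101, 201), c(101, 201)))
  variants$alt <- vapply(variants$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  out <- score_variant_table(list(m1 = w1, m2 = w2), variants, genome,
                             flank_context = 50)
  expect_equal(names(out)[grepl("^vip_", names(out))], c("vip_m1", "vip_m2"))
  # locality: any context beyond l-1 on each side gives identical scores
  out2 <- score_variant_table(list(m1 = w1, m2 = w2), variants, genome,
                              flank_context = 90)
  expect_equal(out$vip_m1, out2$vip_m1, tolerance = 1e-9)
  expect_equal(out$vip_m2, out2$vip_m2, tolerance = 1e-9)

  bad <- dplyr::mutate(variants, ref = c("A", "C"))
  bad$ref[1] <- setdiff(c("A", "C", "G", "T"), substr(genome, 101, 101))[1]
  expect_error(score_variant_table(list(m1 = w1), bad, genome, 50), "v1")

  # an indel goes through whole-context rescoring
  indel <- tibble::tibble(id = "d1", chrom = "chr1", pos = 150L,
                          ref = substr(genome, 151, 158), alt = "")
  sc <- score_variant_table(list(m1 = w1), indel, genome, flank_context = 50)
  ref_ctx <- genome_subseq(genome, "chr1", 100, 208)
  alt_ctx <- apply_variant(ref_ctx, 50, indel$ref, "")
  expect_equal(sc$vip_m1, delta_svm_indel(w1, ref_ctx, alt_ctx), tolerance = 1e-9)
})
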
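test_that("motif sets are seeded, sharp and mutually distinct", {
  spec <- small_spec()
  m1 <- make_motif_set(spec)
  m2 <- make_motif_set(spec)
  expect_identical(m1, m2)
  expect_equal(nrow(m1), 3 * 2 - 1 + 1)  # overlap 1 shared + housekeeping

  # pairwise consensus Hamming >= half the motif length (both strands)
  cons <- m1$consensus
  ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  for (i in seq_along(cons)) for (j in seq_along(cons)) if (i < j) {
    expect_gte(min(ham(cons[i], cons[j]),
                   ham(cons[i], reverse_complement(cons[j]))), 4)
  }

  # consensus scores 100% of the PWM maximum against itself
  for (i in seq_len(nrow(m1))) {
    hits <- match_pwm_to_kmer(m1$pfm[[i]], m1$consensus[i], threshold_frac = 1)
    expect_gte(nrow(hits), 1L)
  }

  # average information content at least 1 bit per position
  ic <- vapply(m1$pfm, function(p) {
    probs <- sweep(p, 2, colSums(p), "/")
    mean(2 + colSums(ifelse(probs > 0, probs * log2(probs), 0)))
  }, numeric(1))
  expect_true(all(ic >= 1))
})

test_that("simulated peaks carry their grammar and a shared universal fraction", {
  sim <- get_small_sim()
  spec <- small_spec()
  peaks <- sim$peaks

  expect_equal(dplyr::count(peaks, class)$n, rep(60L, 3))

  # universal slots: identical summit coordinates across all classes
  by_summit <- dplyr::count(dplyr::distinct(peaks, chrom, summit, class),
                            chrom, summit)
  expect_equal(sum(by_summit$n == 3), floor(0.1 * 60))

  # cross-module: remove_universal after extension drops exactly those
  ext <- extend_summits(peaks, sim$genome, flank = 50)
  ru <- remove_universal(ext)
  expect_equal(nrow(ru$universal), 3 * floor(0.1 * 60))
  expect_equal(dplyr::count(ru$filtered, class)$n, rep(54L, 3))

  # background GC concentrates near the requested level
  withr::with_seed(1, {
    starts <- sample(0:(nchar(sim$genome[1]) - 301), 60)
  })
  gcs <- gc_content(genome_subseq(sim$genome, "chr1", starts, starts + 301))
  expect_lt(abs(mean(gcs) - spec$background_gc), 0.02)
  expect_lt(max(abs(gcs - spec$background_gc)), 0.12)

  # planted instances sit inside their regions and reproduce the
  # consensus up to PFM sampling (mismatch rate ~ 1 - consensus prob)
  inst <- sim$truth$instances
  expect_true(all(inst$offset >= 0 & inst$offset + 8 <= 101))
  seqs <- genome_subseq(sim$genome, inst$chrom, inst$region_start + inst$offset,
                        inst$region_start + inst$offset + 8)
  oriented <- ifelse(inst$strand == "-", reverse_complement(seqs), seqs)
  mism <- purrr::map2_dbl(oriented, inst$motif_id, function(s, id) {
    cons <- sim$motifs$consensus[sim$motifs$motif_id == id]
    mean(strsplit(s, "")[[1]] != strsplit(cons, "")[[1]])
  })
  expect_gt(mean(mism), 0.02)   # instances vary (sampled, not consensus)
  expect_lt(mean(mism), 0.25)   # but stay close to the consensus
  expect_gt(mean(mism <= 0.5), 0.99)
})

test_that("study regeneration and emission are byte-identical under one seed", {
  spec <- synthetic_spec(n_classes = 2, peaks_per_class = 20, region_width = 101,
                         genome_length = 1e5, seed = 99)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_synthetic_study(simulate_genome_and_peaks(spec), d1)
  write_synthetic_study(simulate_genome_and_peaks(spec), d2)
  f1 <- list.files(d1, full.names = TRUE); f2 <- list.files(d2, full.names = TRUE)
  expect_equal(basename(f1), basename(f2))
  expect_equal(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))

  # written formats read back into the pipeline's own types
  g <- read_genome_fasta(file.path(d1, "genome.fa"))
  expect_equal(g, simulate_genome_and_peaks(spec)$genome)
  pk <- read_narrowpeak(file.path(d1, "classA.narrowPeak"))
  expect_equal(nrow(pk), 20L)
  expect_true(all(pk$summit > pk$start & pk$summit < pk$end))
  mo <- read_jaspar_pfm(file.path(d1, "motifs.jaspar"))
  expect_equal(mo$motif_id, make_motif_set(spec)$motif_id)
})

test_that("variant panels are balanced, seeded and reference-consistent", {
  sim <- get_small_sim()
  p1 <- make_variant_panel(sim, n_in_motif = 15, n_background = 15, seed = 5)
  p2 <- make_variant_panel(sim, n_in_motif = 15, n_background = 15, seed = 5)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 30L)
  expect_equal(sum(p1$category == "in_motif"), 15L)
  expect_true(all(p1$ref != p1$alt))
  obs <- genome_subseq(sim$genome, p1$chrom, p1$pos, p1$pos + 1)
  expect_equal(obs, p1$ref)

  expect_error(make_variant_panel(sim, n_in_motif = 1e6, n_background = 1),
               "not enough")
})
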
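toy_regions <- function(starts, chrom = "chr1", score = 1, class = NULL, width = 10L) {
  df <- tibble::tibble(chrom = chrom, start = as.integer(starts),
                       end = as.integer(starts) + width, score = score,
                       name = paste0("r", seq_along(starts)), strand = ".")
  if (!is.null(class)) df$class <- class
  df
}

test_that("summit extension produces fixed-width regions and drops clipped peaks", {
  pk <- tibble::tibble(chrom = "chr1", start = c(900L, 0L), end = c(1100L, 120L),
                       name = c("a", "b"), score = c(1, 2), strand = ".",
                       summit = c(1000L, 50L))
  sizes <- c(chr1 = 10000L)
  expect_message(ext <- extend_summits(pk, sizes, flank = 150), "dropped 1")
  expect_equal(nrow(ext), 1L)
  expect_equal(ext$start, 850L)
  expect_equal(ext$end, 1151L)
  expect_equal(ext$end - ext$start, 301L)

  ext0 <- extend_summits(pk[1, ], sizes, flank = 0)
  expect_equal(ext0$end - ext0$start, 1L)

  expect_error(extend_summits(dplyr::select(pk, -summit), sizes), "summit")
})

test_that("universal regions are those overlapping every other class", {
  peaks <- dplyr::bind_rows(
    toy_regions(c(100, 300), class = "A"),
    toy_regions(c(100, 500), class = "B"),
    toy_regions(c(100, 700), class = "C")
  )
  ru <- remove_universal(peaks)
  expect_equal(nrow(ru$universal), 3L)          # start=100 removed from all 3
  expect_true(all(ru$universal$start == 100))
  expect_equal(sort(ru$filtered$start), c(300, 500, 700))  # private retained

  # 1 bp overlap across 2 classes counts at min_overlap_bp = 1
  two <- dplyr::bind_rows(
    toy_regions(0, class = "A", width = 10),   # [0,10)
    toy_regions(9, class = "B", width = 10)    # [9,19) -> 1 bp shared
  )
  ru2 <- remove_universal(two, min_overlap_bp = 1)
  expect_equal(nrow(ru2$universal), 2L)
  expect_equal(nrow(ru2$filtered), 0L)
  ru3 <- remove_universal(two, min_overlap_bp = 2)
  expect_equal(nrow(ru3$universal), 0L)

  expect_error(remove_universal(toy_regions(1, class = "A")), "single")
})

test_that("top selection ranks by score with coordinate tie-breaks", {
  pk <- toy_regions(c(50, 40, 30, 20, 10))
  pk$score <- c(3, 7, 9, 7, 1)
  top <- select_top(pk, 3)
  expect_equal(top$score, c(9, 7, 7))
  expect_equal(top$start, c(30, 20, 40))  # tie at 7 broken by start
  expect_equal(nrow(select_top(pk, 100)), 5L)
  expect_error(select_top(pk, 0), "positive")

  ties <- toy_regions(c(5, 3, 1), score = 2)
  expect_equal(select_top(ties, 2)$start, c(1, 3))
})

test_that("train/outgroup split conserves regions and is seed-deterministic", {
  pk <- toy_regions(seq(0, 990, by = 10), class = "A")
  sp <- split_train_outgroup(pk, 0.8, seed = 3)
  expect_equal(sum(sp$partition == "train"), 80L)
  expect_equal(sum(sp$partition == "outgroup"), 20L)
  expect_equal(nrow(sp), nrow(pk))
  sp2 <- split_train_outgroup(pk, 0.8, seed = 3)
  expect_identical(sp, sp2)
  sp3 <- split_train_outgroup(pk, 0.8, seed = 4)
  expect_false(identical(sp$partition, sp3$partition))
  expect_warning(split_train_outgroup(pk, 1.0, seed = 1), "empty")
})

test_that("uniform test set removes engineered train collisions exactly", {
  # 6 regions over 2 classes; 2 outgroup regions engineered to collide
  # with the *other* class's training regions
  peaks <- dplyr::bind_rows(
    tibble::tibble(chrom = "chr1", start = c(0L, 100L, 205L), end = c(10L, 110L, 215L),
                   class = "A", partition = c("train", "train", "outgroup"),
                   name = paste0("a", 1:3), score = 1, strand = "."),
    tibble::tibble(chrom = "chr1", start = c(200L, 300L, 105L), end = c(210L, 310L, 115L),
                   class = "B", partition = c("train", "train", "outgroup"),
                   name = paste0("b", 1:3), score = 1, strand = ".")
  )
  expect_message(uni <- build_uniform_testset(peaks), "removed 2")
  expect_equal(nrow(uni), 0L)

  peaks$start[6] <- 500L; peaks$end[6] <- 510L  # decollide b3
  uni2 <- suppressMessages(build_uniform_testset(peaks))
  expect_equal(uni2$name, "b3")
})

test_that("GC-matched negatives match the positive histogram and avoid peaks", {
  sim <- get_small_sim()
  ext <- extend_summits(sim$peaks, sim$genome, flank = 50)
  pos <- dplyr::filter(ext, class == "classA")[1:40, ]
  neg <- suppressWarnings(
    sample_gc_matched_negatives(pos, sim$genome, ext, bin_width = 0.05, seed = 9))
  expect_equal(unique(neg$end - neg$start), 101L)
  expect_gte(nrow(neg), nrow(pos) - 2)

  # exclusion: zero bp overlap with any accessible region (IRanges oracle)
  ov <- IRanges::findOverlaps(
    GenomicRanges::GRanges(neg$chrom, IRanges::IRanges(neg$start + 1, neg$end)),
    GenomicRanges::GRanges(ext$chrom, IRanges::IRanges(ext$start + 1, ext$end)))
  expect_equal(length(ov), 0L)

  # bin-for-bin histogram match (up to the tolerated per-bin deficit)
  bin <- function(g) floor(g / 0.05)
  pos_gc <- gc_content(genome_subseq(sim$genome, pos$chrom, pos$start, pos$end))
  tp <- table(bin(pos_gc)); tn <- table(bin(neg$gc))
  expect_true(all(names(tn) %in% names(tp)))
  got <- as.integer(tn[names(tp)]); got[is.na(got)] <- 0L
  expect_true(all(abs(as.integer(tp) - got) <= 1))

  neg2 <- suppressWarnings(
    sample_gc_matched_negatives(pos, sim$genome, ext, bin_width = 0.05, seed = 9))
  expect_identical(neg, neg2)
})
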
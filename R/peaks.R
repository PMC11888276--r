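# Peak-set curation: summit extension, universal-region removal,
# score-based selection, train/outgroup splitting, cross-class test-set
# filtering and GC-matched negative sampling.  Multi-class inputs are a
# single tibble with a `class` column; interval logic goes through
# IRanges/GenomicRanges.

regions_to_granges <- function(regions) {
  GenomicRanges::GRanges(
    seqnames = regions$chrom,
    ranges = IRanges::IRanges(start = regions$start + 1L, end = regions$end)
  )
}

overlap_any <- function(query, subject, min_overlap_bp = 1L) {
  if (nrow(subject) == 0) return(rep(FALSE, nrow(query)))
  IRanges::overlapsAny(regions_to_granges(query), regions_to_granges(subject),
                       minoverlap = min_overlap_bp)
}

#' Extend peak summits into fixed-width candidate CREs
#'
#' Each summit is extended by `flank` bp on both sides, giving regions
#' of width `2 * flank + 1`.  Peaks whose extension would run past a
#' contig boundary are dropped (with a message) so that every emitted
#' region has identical width.
#'
#' @param peaks Tibble from [read_narrowpeak()]; must carry `summit`.
#' @param chrom_sizes Named integer vector of contig lengths, or a
#'   genome from [read_genome_fasta()] (lengths are taken from it).
#' @param flank Flank size in bp (default 150, giving 301 bp regions).
#' @return Tibble of equal-width regions (`chrom`, `start`, `end`,
#'   `name`, `score`, `strand`, `summit`, plus any `class` column).
#' @export
extend_summits <- function(peaks, chrom_sizes, flank = 150L) {
  if (!"summit" %in% names(peaks) || any(is.na(peaks$summit))) abort("summit missing")
  if (flank < 0) abort("flank must be >= 0")
  if (is.character(chrom_sizes)) chrom_sizes <- nchar(chrom_sizes)
  out <- peaks |>
    mutate(start = .data$summit - as.integer(flank),
           end = .data$summit + as.integer(flank) + 1L)
  len <- chrom_sizes[out$chrom]
  keep <- out$start >= 0 & !is.na(len) & out$end <= len
  if (any(!keep))
    inform(sprintf("extend_summits: dropped %d peak(s) clipped at contig boundaries", sum(!keep)))
  out[keep, , drop = FALSE]
}

#' Remove universally accessible regions from multi-class peak sets
#'
#' A region is universal when it overlaps (by at least
#' `min_overlap_bp`) some region in every other class's set; such
#' regions are removed from each class and returned separately.  They
#' typically reflect housekeeping regulation and would blur class
#' specificity if left in the training sets.
#'
#' @param peaks Tibble of extended regions with a `class` column
#'   (at least two classes).
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return List with `filtered` (peaks minus universal regions) and
#'   `universal` (the removed rows).
#' @export
remove_universal <- function(peaks, min_overlap_bp = 1L) {
  if (!"class" %in% names(peaks)) abort("peaks must carry a `class` column")
  classes <- unique(peaks$class)
  if (length(classes) < 2) abort("universality is undefined for a single peak set")
  by_class <- split(peaks, peaks$class)
  universal <- purrr::map(classes, function(cl) {
    q <- by_class[[cl]]
    in_all <- Reduce(`&`, purrr::map(setdiff(classes, cl), function(other)
      overlap_any(q, by_class[[other]], min_overlap_bp)))
    q[in_all, , drop = FALSE]
  }) |> bind_rows()
  keys <- paste(universal$class, universal$chrom, universal$start)
  filtered <- peaks[!paste(peaks$class, peaks$chrom, peaks$start) %in% keys, , drop = FALSE]
  list(filtered = filtered, universal = universal)
}

#' Keep the top-scoring peaks of each class
#'
#' Peaks are ranked by score (descending) with ties broken by
#' (chrom, start) ascending for determinism.  When a class has fewer
#' than `n` peaks the whole class is kept, with a message.
#'
#' @param peaks Region tibble with a `score` column; grouped per
#'   `class` when that column is present.
#' @param n Number of peaks to keep per class (default 25000).
#' @return Filtered tibble.
#' @export
select_top <- function(peaks, n = 25000L) {
  if (n <= 0) abort("n must be positive")
  pick <- function(df) {
    df <- arrange(df, desc(.data$score), .data$chrom, .data$start)
    if (nrow(df) < n)
      inform(sprintf("select_top: only %d peak(s) available (requested %d)", nrow(df), n))
    head(df, n)
  }
  if ("class" %in% names(peaks)) {
    peaks |> group_by(.data$class) |> group_modify(~ pick(.x)) |> ungroup() |>
      relocate("class", .after = dplyr::last_col())
  } else pick(peaks)
}

#' Split peaks into training and outgroup partitions
#'
#' A seeded shuffle assigns `floor(train_fraction * n)` regions of each
#' class to `train` and the remainder to `outgroup` (the 80/20 holdout
#' scheme: 25,000 curated peaks yield 20,000 training and 5,000
#' outgroup regions).
#'
#' @param peaks Region tibble (optionally with a `class` column).
#' @param train_fraction Fraction assigned to training (default 0.8).
#' @param seed Integer seed for the shuffle.
#' @return Input tibble with a `partition` column (`train`/`outgroup`).
#' @export
split_train_outgroup <- function(peaks, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction > 1) abort("train_fraction must be in (0, 1]")
  if (nrow(peaks) < 2) abort("need at least 2 peaks to split")
  split_one <- function(df) {
    n_train <- floor(train_fraction * nrow(df))
    idx <- sample.int(nrow(df))
    df$partition <- "outgroup"
    df$partition[idx[seq_len(n_train)]] <- "train"
    df
  }
  with_seed(seed, {
    out <- if ("class" %in% names(peaks)) {
      peaks |> group_by(.data$class) |> group_modify(~ split_one(.x)) |> ungroup() |>
        relocate("class", .after = dplyr::last_col())
    } else split_one(peaks)
  })
  if (!any(out$partition == "outgroup"))
    warn("split_train_outgroup: outgroup partition is empty")
  out
}

#' Cross-filter outgroup regions against all classes' training sets
#'
#' Builds a uniform test universe: any outgroup region overlapping (by
#' at least `min_overlap_bp`) any class's training region is removed,
#' so no model is evaluated on sequence it (or any sibling model) was
#' trained on.
#'
#' @param peaks Partitioned tibble from [split_train_outgroup()] with
#'   `class` and `partition` columns.
#' @param min_overlap_bp Minimum overlap in bp (default 1).
#' @return The outgroup rows that survive the cross-comparison.
#' @export
build_uniform_testset <- function(peaks, min_overlap_bp = 1L) {
  if (!all(c("partition", "class") %in% names(peaks)))
    abort("peaks must carry `class` and `partition` columns")
  train <- filter(peaks, .data$partition == "train")
  out <- filter(peaks, .data$partition == "outgroup")
  hit <- overlap_any(out, train, min_overlap_bp)
  if (any(hit))
    inform(sprintf("build_uniform_testset: removed %d outgroup region(s) colliding with training sets", sum(hit)))
  out[!hit, , drop = FALSE]
}

#' Sample GC-matched negative regions from inaccessible background
#'
#' Candidate windows of the positive-region width are tiled across the
#' genome (step = half width), windows overlapping any excluded
#' accessible region or containing N are discarded, and the remainder
#' are sampled so that the histogram of negative GC fractions (bins of
#' `bin_width`) matches the positive histogram bin for bin.  A deficit
#' of one window in an exhausted bin is tolerated with a warning;
#' larger deficits raise an error naming the bin.
#'
#' @param positives Equal-width region tibble (one class's training set).
#' @param genome Named character vector from [read_genome_fasta()].
#' @param exclude Region tibble of all accessible regions (all classes'
#'   raw peaks, plus any extra exclusion sets such as blacklists).
#' @param bin_width GC-histogram bin width (default 0.05).
#' @param seed Integer seed.
#' @return Tibble of negative regions with `seq` and `gc` columns;
#'   one negative per positive (1:1 ratio) up to tolerated deficits.
#' @export
sample_gc_matched_negatives <- function(positives, genome, exclude,
                                        bin_width = 0.05, seed = 1L) {
  widths <- unique(positives$end - positives$start)
  if (length(widths) != 1) abort("positive regions must share one width")
  w <- widths
  step <- max(1L, w %/% 2L)
  cand <- purrr::imap_dfr(genome, function(seq, chrom) {
    len <- nchar(seq)
    if (len < w) return(tibble())
    starts <- seq.int(0L, len - w, by = step)
    tibble(chrom = chrom, start = starts, end = starts + w)
  })
  cand <- cand[!overlap_any(cand, exclude), , drop = FALSE]
  cand$seq <- genome_subseq(genome, cand$chrom, cand$start, cand$end)
  cand <- cand[!stringr::str_detect(cand$seq, "N"), , drop = FALSE]
  cand$gc <- gc_content(cand$seq)

  gc_bin <- function(g) pmin(floor(g / bin_width), floor(1 / bin_width) - 1e-9)
  pos_gc <- gc_content(genome_subseq(genome, positives$chrom, positives$start, positives$end))
  need <- table(gc_bin(pos_gc))
  cand$bin <- gc_bin(cand$gc)

  with_seed(seed, {
    taken <- purrr::imap(as.list(need), function(n_need, bin) {
      pool <- which(cand$bin == as.numeric(bin))
      if (length(pool) < n_need) {
        deficit <- n_need - length(pool)
        if (deficit > 1)
          abort(sprintf("GC bin [%.2f, %.2f) exhausted: need %d candidate windows, have %d",
                        as.numeric(bin) * bin_width, (as.numeric(bin) + 1) * bin_width,
                        n_need, length(pool)))
        warn(sprintf("GC bin [%.2f, %.2f): short by %d window(s)",
                     as.numeric(bin) * bin_width, (as.numeric(bin) + 1) * bin_width, deficit))
      }
      pool[sample.int(length(pool), min(n_need, length(pool)))]
    })
  })
  idx <- sort(unlist(taken, use.names = FALSE))
  neg <- cand[idx, c("chrom", "start", "end", "seq", "gc"), drop = FALSE]
  neg$name <- paste0("neg_", seq_len(nrow(neg)))
  neg$score <- 0
  neg$strand <- "."
  as_tibble(neg)
}
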
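# Vocabulary analysis: rank the complete l-mer vocabulary of a model,
# take the top fraction, call PWM motifs inside the top k-mers, count
# occurrences, filter by an expressed-TF whitelist, and compute
# cross-model enrichment z-scores.

# -- PWM utilities --------------------------------------------------------

# normalize a PFM to probabilities with a pseudocount of
# `pseudo_frac` x column total, spread equally over the four bases
pfm_to_probs <- function(pfm, pseudo_frac = 0.01) {
  if (any(pfm < 0)) abort("PFM entries must be non-negative")
  cs <- colSums(pfm)
  if (any(cs == 0)) abort("PFM column sums to 0")
  probs <- sweep(pfm + rep(cs * pseudo_frac / 4, each = 4), 2, cs * (1 + pseudo_frac), "/")
  probs
}

#' Log-odds position weight matrix from a PFM
#'
#' log2 of the pseudocounted position probabilities against a uniform
#' background.
#'
#' @param pfm 4 x width count (or frequency) matrix, rows A/C/G/T.
#' @param pseudo_frac Pseudocount as a fraction of each column total
#'   (default 0.01).
#' @return 4 x width log-odds matrix.
#' @export
pwm_logodds <- function(pfm, pseudo_frac = 0.01) {
  log2(pfm_to_probs(pfm, pseudo_frac) / 0.25)
}

#' Maximum attainable log-odds score of a PWM
#'
#' @param pwm Log-odds matrix from [pwm_logodds()].
#' @return Scalar: sum of per-column maxima.
#' @export
pwm_max_score <- function(pwm) sum(apply(pwm, 2, max))

# absolute hit threshold with a small slack so an exact-consensus site
# still passes threshold_frac = 1 despite floating-point rounding
pwm_threshold <- function(pwm, threshold_frac) {
  threshold_frac * pwm_max_score(pwm) - 1e-9
}

#' Consensus sequence of a PFM
#'
#' @param pfm 4 x width matrix, rows A/C/G/T.
#' @return Consensus string (ties broken in A<C<G<T order).
#' @export
pfm_consensus <- function(pfm) {
  paste(DNA_BASES[apply(pfm, 2, which.max)], collapse = "")
}

#' Match a PWM against a k-mer
#'
#' Both strands are scanned; a hit requires a log-odds score of at
#' least `threshold_frac` times the maximum attainable score.  The
#' shorter of the two slides within the longer: when the k-mer is
#' shorter than the motif it is scored against every same-length
#' sub-window of the PWM (reported with negative offsets, the k-mer
#' starting at motif column `-offset`).
#'
#' @param pfm 4 x width count matrix (or one row of a motif tibble's
#'   `pfm` list-column).
#' @param kmer Sequence to match.
#' @param threshold_frac Fraction of the maximum attainable score
#'   (default 0.8).
#' @return Tibble with `offset` (0-based start of the motif within the
#'   k-mer; negative when the k-mer sits inside the motif), `strand`
#'   and `score`.
#' @export
match_pwm_to_kmer <- function(pfm, kmer, threshold_frac = 0.8) {
  if (threshold_frac <= 0 || threshold_frac > 1) abort("threshold_frac must be in (0, 1]")
  pwm <- pwm_logodds(pfm)
  w <- ncol(pwm)
  if (nchar(kmer) >= w) {
    hits <- cpp_pwm_scan(kmer, pwm, pwm_threshold(pwm, threshold_frac))
    return(tibble(offset = hits$offset, strand = hits$strand, score = hits$score))
  }
  len <- nchar(kmer)
  purrr::map_dfr(0:(w - len), function(s) {
    sub <- pwm[, (s + 1):(s + len), drop = FALSE]
    hits <- cpp_pwm_scan(kmer, sub, pwm_threshold(sub, threshold_frac))
    tibble(offset = -s, strand = hits$strand, score = hits$score)[seq_len(nrow(hits)), ]
  })
}

# -- vocabulary ranking ---------------------------------------------------

#' Rank the complete l-mer vocabulary of a model
#'
#' @param weights A `kmer_weights` object (see [extract_kmer_weights()]).
#' @return Tibble with `kmer`, `score`, `rank` (1 = highest), sorted by
#'   descending score with ties broken lexicographically.
#' @export
rank_vocabulary <- function(weights) {
  w <- weights$weights
  ord <- order(-w, seq_along(w))  # code order = lexicographic order
  tibble(kmer = cpp_codes_to_kmers(ord - 1L, weights$l),
         score = w[ord], rank = seq_along(ord))
}

#' Top fraction of a ranked vocabulary
#'
#' @param vocab Ranked tibble from [rank_vocabulary()].
#' @param fraction Fraction of the vocabulary to keep (default 0.01,
#'   the top 1%); the first `floor(fraction * n)` entries.
#' @return Head of `vocab`.
#' @export
top_fraction <- function(vocab, fraction = 0.01) {
  if (fraction <= 0 || fraction > 1) abort("fraction must be in (0, 1]")
  n <- floor(fraction * nrow(vocab))
  if (n == 0) warn("top_fraction: fraction selects zero entries")
  head(vocab, n)
}

#' Count motif occurrences in a top-vocabulary set
#'
#' Counts are total hits over (k-mer, offset, strand) triples, so one
#' k-mer may contribute several occurrences.  When a non-empty
#' whitelist of expressed TF names is given, motifs whose name is
#' absent are dropped.
#'
#' @param top_kmers Character vector of k-mers, or a tibble with a
#'   `kmer` column (as from [top_fraction()]).
#' @param motifs Motif tibble from [read_jaspar_pfm()].
#' @param whitelist Optional character vector of TF names to keep
#'   (`NULL` = no filtering).
#' @param threshold_frac PWM hit threshold (default 0.8).
#' @return Tibble with `motif_id`, `motif_name`, `count`.
#' @export
count_motifs_in_top_vocab <- function(top_kmers, motifs, whitelist = NULL,
                                      threshold_frac = 0.8) {
  if (nrow(motifs) == 0) abort("no motifs supplied")
  if (is.data.frame(top_kmers)) top_kmers <- top_kmers$kmer
  if (!is.null(whitelist) && length(whitelist) > 0)
    motifs <- filter(motifs, .data$motif_name %in% whitelist)
  purrr::pmap_dfr(motifs[c("motif_id", "motif_name", "pfm")],
                  function(motif_id, motif_name, pfm) {
    pwm <- pwm_logodds(pfm)
    n <- if (length(top_kmers) == 0) 0L else {
      if (nchar(top_kmers[1]) >= ncol(pwm)) {
        nrow(cpp_pwm_scan(top_kmers, pwm, pwm_threshold(pwm, threshold_frac)))
      } else {
        sum(vapply(top_kmers, function(km)
          nrow(match_pwm_to_kmer(pfm, km, threshold_frac)), integer(1)))
      }
    }
    tibble(motif_id = motif_id, motif_name = motif_name, count = as.integer(n))
  })
}

#' Motif enrichment z-scores across models
#'
#' Per motif (row), the z-score of each model's count against the
#' row's mean and sample standard deviation; rows with zero SD get
#' z = 0.  Mirrors a motif-by-model enrichment heat map.
#'
#' @param counts Long tibble with `motif_id`, `class` (model label) and
#'   `count` columns, covering at least two models.
#' @return `counts` with a `zscore` column appended.
#' @export
motif_zscores <- function(counts) {
  if (length(unique(counts$class)) < 2)
    abort("z-scores need counts from at least two models")
  counts |>
    group_by(.data$motif_id) |>
    mutate(zscore = if (sd(.data$count) > 0) {
      (.data$count - mean(.data$count)) / sd(.data$count)
    } else rep(0, dplyr::n())) |>
    ungroup()
}
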
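# deltaSVM-style Variant Impact Prediction (VIP): additive sequence
# scoring from the l-mer weight table, SNV and indel scoring, full
# in-silico saturation mutagenesis, summed per-base tracks,
# motif-centered VIP profiles and scoring of external variant tables.

#' Additive sequence score from a k-mer weight table
#'
#' Sum of the weights of all `length - l + 1` sliding l-mers (forward
#' strand; the weights themselves are strand-symmetric when the model
#' counted both strands).
#'
#' @param weights A `kmer_weights` object.
#' @param seq N-free sequence of length >= l.
#' @return Scalar additive score.
#' @export
score_sequence_additive <- function(weights, seq) {
  if (nchar(seq) < weights$l) abort("sequence shorter than l")
  codes <- cpp_lmer_codes(seq, weights$l)
  if (anyNA(codes)) abort("sequence contains N; additive score undefined")
  sum(weights$weights[codes + 1L])
}

#' deltaSVM score of a single-nucleotide variant
#'
#' Sums `weight(alt window) - weight(ref window)` over the at most `l`
#' windows covering the edited position — exactly the difference of
#' the full additive scores of the alternate and reference sequences.
#'
#' @param weights A `kmer_weights` object.
#' @param seq Reference sequence context.
#' @param pos 0-based position of the variant within `seq`.
#' @param alt Alternate base (A/C/G/T).
#' @return The VIP score (negative = predicted loss of activity).
#' @export
delta_svm_snv <- function(weights, seq, pos, alt) {
  l <- weights$l
  L <- nchar(seq)
  if (pos < 0 || pos >= L) abort("pos outside sequence")
  ref <- substr(seq, pos + 1, pos + 1)
  if (identical(ref, alt)) {
    warn("alt equals ref; VIP is 0")
    return(0)
  }
  codes <- cpp_lmer_codes(seq, l)
  w0 <- max(0L, pos - l + 1L); w1 <- min(pos, L - l)
  if (w1 < w0) abort("no l-length window covers pos")
  alt_seq <- seq
  substr(alt_seq, pos + 1, pos + 1) <- alt
  alt_codes <- cpp_lmer_codes(alt_seq, l)
  win <- (w0:w1) + 1L
  if (anyNA(codes[win]) || anyNA(alt_codes[win]))
    abort("N within the scoring windows")
  sum(weights$weights[alt_codes[win] + 1L] - weights$weights[codes[win] + 1L])
}

#' deltaSVM score of an indel or multi-base variant
#'
#' Difference of the full additive scores of the alternate and
#' reference constructs (whole-sequence rescoring, as used for motif
#' deletions matched to reporter constructs).
#'
#' @param weights A `kmer_weights` object.
#' @param ref_seq,alt_seq Reference and alternate sequences (both
#'   N-free, length >= l).
#' @return The VIP score.
#' @export
delta_svm_indel <- function(weights, ref_seq, alt_seq) {
  score_sequence_additive(weights, alt_seq) -
    score_sequence_additive(weights, ref_seq)
}

#' Apply a variant to a sequence (0-based position within the sequence)
#'
#' @param seq Reference sequence.
#' @param pos 0-based start of the reference allele.
#' @param ref Reference allele (must match `seq` at `pos`).
#' @param alt Alternate allele (empty string = pure deletion).
#' @return Edited sequence.
#' @export
apply_variant <- function(seq, pos, ref, alt) {
  obs <- substr(seq, pos + 1, pos + nchar(ref))
  if (obs != ref)
    abort(sprintf("reference allele mismatch at pos %d: sequence has '%s', variant says '%s'",
                  pos, obs, ref))
  paste0(substr(seq, 1, pos), alt, substr(seq, pos + nchar(ref) + 1, nchar(seq)))
}

#' In-silico saturation mutagenesis of a region
#'
#' VIP score of every possible single-nucleotide substitution at every
#' position: 3 alternate alleles per N-free position.
#'
#' @param weights A `kmer_weights` object.
#' @param region Either a sequence string, or a one-row region tibble
#'   with `chrom`, `start`, `end` (then `genome` is required).
#' @param genome Optional genome (named character vector).
#' @return A `vip_table`: tibble with `pos` (0-based within the
#'   region), `ref`, `alt`, `vip`, plus `chrom`/`genome_pos` columns
#'   when the region is genomic.  Positions whose windows all contain N
#'   are absent (with a message).
#' @export
saturation_mutagenesis <- function(weights, region, genome = NULL) {
  if (is.data.frame(region)) {
    stopifnot(nrow(region) == 1)
    if (!"seq" %in% names(region) && is.null(genome))
      abort("genomic region input needs a genome")
    seq <- if ("seq" %in% names(region)) region$seq else
      genome_subseq(genome, region$chrom, region$start, region$end)
    chrom <- region$chrom; offset <- region$start
  } else {
    seq <- region; chrom <- NA_character_; offset <- 0L
  }
  seq <- toupper(seq)
  l <- weights$l
  vip <- cpp_saturation(seq, weights$weights, l)
  refs <- strsplit(seq, "")[[1]]
  tbl <- tibble(
    pos = rep(seq_len(nchar(seq)) - 1L, each = 4L),
    ref = rep(refs, each = 4L),
    alt = rep(DNA_BASES, nchar(seq)),
    vip = as.vector(vip)
  ) |> filter(.data$ref != .data$alt)
  n_na <- sum(is.na(tbl$vip))
  if (n_na > 0) {
    inform(sprintf("saturation_mutagenesis: %d entr(ies) skipped at N positions", n_na))
    tbl <- filter(tbl, !is.na(.data$vip))
  }
  if (!is.na(chrom)) {
    tbl <- mutate(tbl, chrom = chrom, genome_pos = .data$pos + offset, .before = 1)
  }
  structure(tbl, class = c("vip_table", class(tbl)),
            ref_sequence = seq, model = weights$class_label)
}

#' Summed per-position VIP track
#'
#' Sums the three alternate-allele VIP scores at each position — the
#' per-base track plotted over candidate CREs.
#'
#' @param vip A `vip_table` from [saturation_mutagenesis()].
#' @return Tibble with `pos` (and `chrom`/`genome_pos` when genomic)
#'   and `value`; ready for [write_bedgraph()] after renaming
#'   `genome_pos` to `pos`.
#' @export
summed_vip_track <- function(vip) {
  grp <- intersect(c("chrom", "genome_pos", "pos"), names(vip))
  vip |>
    group_by(across(all_of(grp))) |>
    summarise(value = sum(.data$vip), .groups = "drop")
}

#' Scan regions for motif occurrences
#'
#' All PWM hits (both strands) scoring at least `threshold_frac` of
#' the motif's maximum attainable log-odds score.  Palindromic double
#' hits at one locus are collapsed to the forward-strand occurrence.
#'
#' @param regions Region tibble with `chrom`, `start`, `end` (a `seq`
#'   column is used if present, else extracted from `genome`).
#' @param genome Named character vector (optional when `seq` present).
#' @param motifs Motif tibble from [read_jaspar_pfm()].
#' @param threshold_frac Hit threshold (default 0.8).
#' @return Tibble with `motif_id`, `chrom`, `start`, `end`, `strand`,
#'   `score` (genomic, 0-based half-open), deduplicated across
#'   overlapping regions.
#' @export
scan_motif_occurrences <- function(regions, genome = NULL, motifs,
                                   threshold_frac = 0.8) {
  if (!"seq" %in% names(regions)) regions <- region_sequences(regions, genome)
  purrr::pmap_dfr(motifs[c("motif_id", "pfm")], function(motif_id, pfm) {
    pwm <- pwm_logodds(pfm)
    hits <- cpp_pwm_scan(regions$seq, pwm, pwm_threshold(pwm, threshold_frac))
    if (nrow(hits) == 0) return(tibble())
    tibble(
      motif_id = motif_id,
      chrom = regions$chrom[hits$seq_index],
      start = regions$start[hits$seq_index] + hits$offset,
      end = regions$start[hits$seq_index] + hits$offset + ncol(pwm),
      strand = hits$strand, score = hits$score
    )
  }) |>
    arrange(.data$motif_id, .data$chrom, .data$start, .data$strand) |>
    distinct(.data$motif_id, .data$chrom, .data$start, .keep_all = TRUE)
}

#' Motif-centered average VIP profile
#'
#' For each offset relative to the motif start (from `-window` to
#' `motif_length - 1 + window`, in motif orientation), the mean VIP
#' over all occurrences and all three alternate alleles.  Minus-strand
#' occurrences are flipped so that offset 0 is always the motif's 5'
#' end.
#'
#' @param vips A list of `vip_table`s covering genomic regions (or one
#'   combined tibble with `chrom` and `genome_pos`).
#' @param occurrences Tibble from [scan_motif_occurrences()] (one
#'   motif, or grouped per `motif_id`).
#' @param window Flank width in bp (default 30; use 25 for the
#'   narrower presentation).
#' @return Tibble with `motif_id`, `offset`, `mean_vip`, `n`
#'   (occurrences contributing).
#' @export
motif_vip_profile <- function(vips, occurrences, window = 30L) {
  if (nrow(occurrences) == 0) abort("no motif occurrences supplied")
  vip_all <- if (is.data.frame(vips)) vips else bind_rows(vips)
  if (!all(c("chrom", "genome_pos") %in% names(vip_all)))
    abort("vip tables must be genomic (carry chrom and genome_pos)")
  occurrences <- mutate(occurrences, occ_id = dplyr::row_number())
  width <- occurrences$end - occurrences$start
  grid <- tidyr::crossing(occ_id = occurrences$occ_id,
                          offset = seq(-window, max(width) - 1 + window)) |>
    left_join(occurrences, by = "occ_id") |>
    filter(.data$offset <= .data$end - .data$start - 1 + window) |>
    mutate(genome_pos = ifelse(.data$strand == "-",
                               .data$end - 1L - .data$offset,
                               .data$start + .data$offset))
  joined <- inner_join(grid, vip_all, by = c("chrom", "genome_pos"),
                       relationship = "many-to-many")
  dropped <- setdiff(occurrences$occ_id, unique(joined$occ_id))
  if (length(dropped) == nrow(occurrences))
    abort("no occurrence is covered by the supplied VIP tables")
  if (length(dropped) > 0)
    inform(sprintf("motif_vip_profile: %d occurrence(s) outside VIP coverage skipped", length(dropped)))
  joined |>
    group_by(.data$motif_id, .data$offset) |>
    summarise(mean_vip = mean(.data$vip),
              n = dplyr::n_distinct(.data$occ_id), .groups = "drop") |>
    arrange(.data$motif_id, .data$offset)
}

#' Score a variant table with one or more models
#'
#' Each variant is scored on a context window of `flank_context` bp on
#' each side: SNVs by windowed deltaSVM, indels and multi-base
#' variants by whole-context rescoring.  When motifs are supplied, the
#' motif names hit in the reference and alternate contexts are
#' appended.
#'
#' @param weight_sets Named list of `kmer_weights` (one per model).
#' @param variants Variant tibble from [read_variant_table()].
#' @param genome Named character vector.
#' @param flank_context Context half-width in bp (default 150).
#' @param motifs Optional motif tibble for annotation.
#' @param threshold_frac Motif hit threshold (default 0.8).
#' @return Tibble: variant columns plus one `vip_<model>` column per
#'   model and, when annotated, `motifs_ref`/`motifs_alt`.
#' @export
score_variant_table <- function(weight_sets, variants, genome,
                                flank_context = 150L, motifs = NULL,
                                threshold_frac = 0.8) {
  if (is.null(names(weight_sets))) abort("weight_sets must be a named list")
  l <- weight_sets[[1]]$l
  if (flank_context < l - 1) abort("flank_context must be at least l - 1")
  ctx <- purrr::pmap_dfr(variants, function(id, chrom, pos, ref, alt, ...) {
    len <- nchar(genome[[chrom]])
    s <- max(0L, pos - flank_context)
    e <- min(len, pos + nchar(ref) + flank_context)
    seq <- genome_subseq(genome, chrom, s, e)
    obs <- substr(seq, pos - s + 1, pos - s + nchar(ref))
    if (obs != ref)
      abort(paste0("reference allele mismatch vs genome for variant: ", id))
    tibble(id = id, ref_context = seq, ctx_pos = pos - s,
           alt_context = apply_variant(seq, pos - s, ref, alt))
  })
  out <- bind_cols(variants, ctx[c("ref_context", "alt_context", "ctx_pos")])
  for (m in names(weight_sets)) {
    w <- weight_sets[[m]]
    out[[paste0("vip_", m)]] <- purrr::pmap_dbl(
      out[c("ref_context", "alt_context", "ctx_pos", "ref", "alt")],
      function(ref_context, alt_context, ctx_pos, ref, alt) {
        if (nchar(ref) == 1 && nchar(alt) == 1) {
          delta_svm_snv(w, ref_context, ctx_pos, alt)
        } else {
          delta_svm_indel(w, ref_context, alt_context)
        }
      })
  }
  if (!is.null(motifs)) {
    annotate <- function(seqs) vapply(seqs, function(s) {
      hit <- purrr::pmap_lgl(motifs[c("pfm",  "motif_id")], function(pfm, motif_id) {
        pwm <- pwm_logodds(pfm)
        nrow(cpp_pwm_scan(s, pwm, pwm_threshold(pwm, threshold_frac))) > 0
      })
      paste(motifs$motif_name[hit], collapse = ",")
    }, "")
    out$motifs_ref <- annotate(out$ref_context)
    out$motifs_alt <- annotate(out$alt_context)
  }
  out
}
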
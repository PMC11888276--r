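# Shared internal helpers: sequence utilities, seeded evaluation,
# coordinate conversion.  All genomic coordinates in this package are
# 0-based half-open (BED convention); `to_zero_based()` is the single
# place 1-based input is translated.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA sequences
#'
#' @param x Character vector of sequences over A/C/G/T/N (case kept upper).
#' @return Character vector of reverse complements.
#' @export
#' @examples
#' reverse_complement("ACGTT")
reverse_complement <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' GC fraction of sequences
#'
#' Fraction of G or C bases over the full sequence length (N counts
#' toward the denominator).
#'
#' @param x Character vector of sequences.
#' @return Numeric vector in \[0, 1\].
#' @export
#' @examples
#' gc_content("ACGT")
gc_content <- function(x) {
  stringr::str_count(toupper(x), "[GC]") / nchar(x)
}

#' Convert positions to the internal 0-based convention
#'
#' @param pos Integer positions.
#' @param one_based Set `TRUE` when `pos` is 1-based (e.g. GWAS tables).
#' @return 0-based integer positions.
#' @export
to_zero_based <- function(pos, one_based = FALSE) {
  if (one_based) pos - 1L else as.integer(pos)
}

# evaluate `code` under a fixed seed without disturbing the caller's RNG
with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# validate that sequences are N-free, upper-case DNA of minimum length
check_sequences <- function(seqs, min_len = 1L, what = "sequence") {
  if (length(seqs) == 0) abort(paste0("no ", what, "s supplied"))
  if (any(is.na(seqs))) abort(paste0("NA ", what))
  bad <- nchar(seqs) < min_len
  if (any(bad))
    abort(sprintf("%d %s(s) shorter than %d bp", sum(bad), what, min_len))
  if (any(stringr::str_detect(seqs, "[^ACGT]")))
    abort(paste0(what, "s must contain only A/C/G/T (no N)"))
  invisible(seqs)
}

# pull a sequence column out of a data frame, or pass a character vector
as_seqs <- function(x) {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (!"seq" %in% names(x)) abort("data frame input must carry a `seq` column")
    return(x$seq)
  }
  abort("expected a character vector or a data frame with a `seq` column")
}
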
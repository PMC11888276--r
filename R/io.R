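# Readers and writers for every external format the workflow touches:
# narrowPeak/BED peak calls, genome FASTA, JASPAR PFM text, bedGraph
# tracks, variant TSV, MPRA TSV.  All tabular values come back as
# tibbles with 0-based half-open coordinates.

#' Read ENCODE narrowPeak or BED peak calls
#'
#' Accepts 10-column ENCODE narrowPeak or plain BED with at least 3
#' columns.  The summit is taken from the narrowPeak offset column when
#' present and non-negative (macs2 writes -1 when summits were not
#' called); otherwise it falls back to the interval midpoint.
#'
#' @param path Path to a tab-separated peak file.  Lines starting with
#'   `#`, `track` or `browser` are skipped.
#' @return A tibble with columns `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit` (all coordinates 0-based half-open,
#'   `summit` an absolute 0-based position).  Input row order preserved.
#' @export
read_narrowpeak <- function(path) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  lines <- readr::read_lines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0)
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  name = character(), score = double(), strand = character(),
                  summit = integer()))
  fields <- stringr::str_split(lines, "\t")
  ncols <- lengths(fields)
  if (any(ncols < 3))
    abort(sprintf("malformed line %d: fewer than 3 columns", lineno[which(ncols < 3)[1]]))
  n <- length(fields)
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  start <- suppressWarnings(as.integer(col(2)))
  end <- suppressWarnings(as.integer(col(3)))
  bad <- which(is.na(start) | is.na(end))
  if (length(bad))
    abort(sprintf("malformed line %d: non-numeric coordinates", lineno[bad[1]]))
  if (any(start < 0))
    abort(sprintf("malformed line %d: negative start coordinate", lineno[which(start < 0)[1]]))
  if (any(end <= start))
    abort(sprintf("malformed line %d: end <= start", lineno[which(end <= start)[1]]))
  name <- col(4)
  name[is.na(name) | name == "."] <- paste0("peak_", seq_len(n))[is.na(name) | name == "."]
  score <- suppressWarnings(as.numeric(col(5)))
  score[is.na(score)] <- 0
  strand <- col(6)
  strand[is.na(strand) | !strand %in% c("+", "-")] <- "."
  peak <- if (all(ncols >= 10)) suppressWarnings(as.integer(col(10))) else rep(NA_integer_, n)
  summit <- ifelse(!is.na(peak) & peak >= 0, start + peak, (start + end) %/% 2L)
  tibble(chrom = col(1), start = start, end = end, name = name,
         score = score, strand = strand, summit = as.integer(summit))
}

#' Write regions as BED6 (+ summit offset column)
#'
#' @param regions Tibble with `chrom`, `start`, `end` and optionally
#'   `name`, `score`, `strand`, `summit`.
#' @param path Output path.
#' @param sort Sort by (chrom, start) before writing.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path, sort = TRUE) {
  stopifnot(all(c("chrom", "start", "end") %in% names(regions)))
  pick <- function(col, default) {
    if (col %in% names(regions)) regions[[col]] else default
  }
  out <- tibble(
    chrom = regions$chrom, start = regions$start, end = regions$end,
    name = pick("name", paste0("region_", seq_len(nrow(regions)))),
    score = pick("score", 0),
    strand = pick("strand", ".")
  )
  if ("summit" %in% names(regions)) out$summit_offset <- regions$summit - regions$start
  if (sort) out <- arrange(out, .data$chrom, .data$start)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a genome FASTA into a named vector of upper-case sequences
#'
#' @param path FASTA path.
#' @param ambiguous How to treat characters outside A/C/G/T/N: map to
#'   `"N"` (default) or `"error"`.
#' @return Named character vector, one entry per contig (header text up
#'   to the first whitespace).
#' @export
read_genome_fasta <- function(path, ambiguous = c("N", "error")) {
  ambiguous <- match.arg(ambiguous)
  set <- Biostrings::readDNAStringSet(path)
  nm <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(nm)) abort(paste0("duplicate FASTA header: ", nm[duplicated(nm)][1]))
  if (any(Biostrings::width(set) == 0))
    abort(paste0("empty FASTA record: ", nm[Biostrings::width(set) == 0][1]))
  seqs <- toupper(as.character(set))
  other <- stringr::str_detect(seqs, "[^ACGTN]")
  if (any(other)) {
    if (ambiguous == "error") abort("genome contains characters outside A/C/G/T/N")
    seqs <- stringr::str_replace_all(seqs, "[^ACGTN]", "N")
  }
  setNames(seqs, nm)
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector (or tibble with `name`/`seq`).
#' @param path Output path.
#' @export
write_fasta <- function(seqs, path) {
  if (is.data.frame(seqs)) seqs <- setNames(seqs$seq, seqs$name)
  set <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 80L)
  invisible(path)
}

#' Extract a genome subsequence (0-based half-open)
#'
#' @param genome Named character vector from [read_genome_fasta()].
#' @param chrom,start,end Coordinates; vectors recycle.
#' @return Character vector of sequences.
#' @export
#' @examples
#' genome_subseq(c(chr1 = "ACGT"), "chr1", 1, 3)  # "CG"
genome_subseq <- function(genome, chrom, start, end) {
  miss <- setdiff(unique(chrom), names(genome))
  if (length(miss)) abort(paste0("chromosome not in genome: ", miss[1]))
  len <- nchar(genome[chrom])
  if (any(start < 0) || any(end > len) || any(end <= start))
    abort("requested interval outside contig bounds")
  unname(stringr::str_sub(genome[chrom], start + 1, end))
}

#' Attach region sequences from a genome
#'
#' @param regions Tibble with `chrom`, `start`, `end`.
#' @param genome Named character vector.
#' @return `regions` with a `seq` column appended.
#' @export
region_sequences <- function(regions, genome) {
  mutate(regions, seq = genome_subseq(genome, .data$chrom, .data$start, .data$end))
}

#' Read JASPAR-format position frequency matrices
#'
#' Parses the JASPAR text format: a `>ID NAME` header followed by four
#' rows (A, C, G, T) of counts, with or without `[ ]` brackets.  When
#' the header carries no name token the id doubles as the name.
#'
#' @param path PFM file path.
#' @return Tibble with `motif_id`, `motif_name` and a `pfm` list-column
#'   of 4 x width numeric matrices (rows A/C/G/T, columns 5'->3').
#' @export
read_jaspar_pfm <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  heads <- grep("^>", lines)
  if (length(heads) == 0) abort("no '>' headers found; not JASPAR PFM text")
  blocks <- Map(function(s, e) lines[s:e], heads,
                c(heads[-1] - 1L, length(lines)))
  rows <- purrr::map(blocks, function(b) {
    hdr <- sub("^>\\s*", "", b[1])
    toks <- strsplit(trimws(hdr), "\\s+")[[1]]
    id <- toks[1]
    nm <- if (length(toks) >= 2) toks[2] else id
    body <- b[-1]
    if (length(body) != 4)
      abort(sprintf("motif %s: expected 4 base rows, found %d", id, length(body)))
    parse_row <- function(x) {
      x <- gsub("\\[|\\]", " ", x)
      m <- regmatches(x, regexpr("^\\s*([ACGTacgt])\\b", x))
      base <- toupper(trimws(sub("\\s.*$", "", x)))
      base <- substr(base, 1, 1)
      vals <- suppressWarnings(as.numeric(strsplit(trimws(sub("^\\s*[ACGTacgt]\\s*", "", x)), "\\s+")[[1]]))
      if (!base %in% DNA_BASES) abort(sprintf("motif %s: unknown base row '%s'", id, base))
      if (any(is.na(vals))) abort(sprintf("motif %s: non-numeric counts", id))
      list(base = base, vals = vals)
    }
    parsed <- lapply(body, parse_row)
    bases <- vapply(parsed, `[[`, "", "base")
    if (!setequal(bases, DNA_BASES))
      abort(sprintf("motif %s: base rows are %s, need A,C,G,T", id, paste(bases, collapse = ",")))
    lens <- lengths(lapply(parsed, `[[`, "vals"))
    if (length(unique(lens)) != 1)
      abort(sprintf("motif %s: rows of unequal length", id))
    mat <- do.call(rbind, lapply(parsed, `[[`, "vals"))[match(DNA_BASES, bases), , drop = FALSE]
    rownames(mat) <- DNA_BASES
    if (any(mat < 0)) abort(sprintf("motif %s: negative counts", id))
    if (any(colSums(mat) == 0)) abort(sprintf("motif %s: column with zero total count", id))
    tibble(motif_id = id, motif_name = nm, pfm = list(mat))
  })
  bind_rows(rows)
}

#' Write motifs in JASPAR PFM text format
#'
#' @param motifs Tibble as returned by [read_jaspar_pfm()].
#' @param path Output path.
#' @export
write_jaspar_pfm <- function(motifs, path) {
  out <- purrr::pmap(motifs[c("motif_id", "motif_name", "pfm")], function(motif_id, motif_name, pfm) {
    c(paste0(">", motif_id, " ", motif_name),
      vapply(DNA_BASES, function(b)
        paste0(b, " [ ", paste(format(pfm[b, ], trim = TRUE), collapse = " "), " ]"), ""))
  })
  readr::write_lines(unlist(out), path)
  invisible(path)
}

#' Write a per-base score track as bedGraph
#'
#' One line per position (single-base intervals), sorted by chromosome
#' then start.
#'
#' @param track Tibble with `chrom`, `pos` (0-based) and `value`.
#' @param path Output path.
#' @export
write_bedgraph <- function(track, path) {
  stopifnot(all(c("chrom", "pos", "value") %in% names(track)))
  if (anyDuplicated(track[c("chrom", "pos")]))
    abort("duplicate (chrom, pos) entries in track")
  out <- track |>
    arrange(.data$chrom, .data$pos) |>
    transmute(.data$chrom, start = .data$pos, end = .data$pos + 1L, .data$value)
  readr::write_tsv(out, path, col_names = FALSE)
  invisible(path)
}

#' Read a bedGraph written by [write_bedgraph()]
#'
#' @param path bedGraph path.
#' @return Tibble with `chrom`, `pos`, `value` (single-base intervals
#'   are expanded positionwise).
#' @export
read_bedgraph <- function(path) {
  df <- readr::read_tsv(path, col_names = c("chrom", "start", "end", "value"),
                        col_types = "ciid", comment = "#")
  purrr::pmap_dfr(df, function(chrom, start, end, value)
    tibble(chrom = chrom, pos = seq(start, end - 1L), value = value))
}

#' Read a variant table (TSV)
#'
#' Expects a header with columns `id`, `chrom`, `pos`, `ref`, `alt`.
#' An empty/`-`/missing alt encodes a pure deletion.
#'
#' @param path TSV path.
#' @param one_based Set `TRUE` when `pos` is 1-based.
#' @param genome Optional genome to validate the reference allele.
#' @return Tibble with 0-based `pos`.
#' @export
read_variant_table <- function(path, one_based = FALSE, genome = NULL) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"), comment = "#")
  need <- c("id", "chrom", "pos", "ref", "alt")
  if (!all(need %in% names(df)))
    abort(paste0("variant table must carry columns: ", paste(need, collapse = ", ")))
  out <- tibble(
    id = df$id, chrom = df$chrom,
    pos = to_zero_based(as.integer(df$pos), one_based),
    ref = toupper(df$ref),
    alt = toupper(ifelse(is.na(df$alt) | df$alt %in% c("-", "."), "", df$alt))
  )
  if (any(is.na(out$pos) | out$pos < 0)) abort("invalid variant positions")
  if (any(!nzchar(out$ref)) || any(stringr::str_detect(out$ref, "[^ACGT]")))
    abort("reference alleles must be non-empty A/C/G/T strings")
  if (any(stringr::str_detect(out$alt, "[^ACGT]")))
    abort("alternate alleles must be A/C/G/T strings (empty = deletion)")
  if (!is.null(genome)) {
    obs <- genome_subseq(genome, out$chrom, out$pos, out$pos + nchar(out$ref))
    bad <- obs != out$ref
    if (any(bad))
      abort(paste0("reference allele mismatch vs genome for variant: ",
                   paste(out$id[bad], collapse = ", ")))
  }
  out
}

#' Read an MPRA result table (TSV)
#'
#' Requires `variant_id` and `cell_class` plus either a precomputed
#' `expression_change` column or the pair `variant_expression` /
#' `reference_expression` to difference.
#'
#' @param path TSV path.
#' @return Tibble with `variant_id`, `cell_class`, `expression_change`
#'   and, when available, `reference_expression`.
#' @export
read_mpra_table <- function(path) {
  df <- readr::read_tsv(path, show_col_types = FALSE, comment = "#")
  if (!all(c("variant_id", "cell_class") %in% names(df)))
    abort("MPRA table must carry variant_id and cell_class")
  if (!"expression_change" %in% names(df)) {
    if (!all(c("variant_expression", "reference_expression") %in% names(df)))
      abort("MPRA table needs expression_change or variant_expression + reference_expression")
    df$expression_change <- df$variant_expression - df$reference_expression
  }
  if (anyDuplicated(df[c("variant_id", "cell_class")]))
    abort("duplicate (variant_id, cell_class) rows in MPRA table")
  if (any(!is.finite(df$expression_change))) abort("non-finite expression changes")
  as_tibble(df)
}
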
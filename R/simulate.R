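# Synthetic multi-class study generator: a random genome, per-class
# peak sets with planted class-specific motif grammars and a shared
# universally-accessible fraction, sharp PFMs, variant panels, and a
# simulated reporter assay whose expression is a known linear function
# of motif content.  Everything is seeded and regenerates
# byte-identically.

#' Specification of a synthetic multi-class accessibility study
#'
#' Defaults describe the standing benchmark: three cell classes of 500
#' peaks each, 301 bp regions (the +/-150 bp summit extension width),
#' a 2 Mb background genome at 41% GC (human-like), two sharp 8 bp
#' motifs per class grammar, one to three motif insertions per peak,
#' and a 10% universally accessible fraction carrying a housekeeping
#' motif.
#'
#' @param n_classes Number of cell classes.
#' @param peaks_per_class Peaks per class (universal peaks included).
#' @param region_width Candidate-CRE width in bp (odd).
#' @param genome_length Total background genome length in bp (split
#'   over two chromosomes).
#' @param background_gc Background GC fraction.
#' @param motifs_per_class Class-specific motifs per grammar.
#' @param motif_length Motif width in bp.
#' @param insertions_per_peak Integer range `c(min, max)` of motif
#'   instances planted per private peak.
#' @param shared_fraction Fraction of each class's peaks that are
#'   universal (identical across classes).
#' @param grammar_overlap Number of motifs the first two classes share
#'   (default 1), emulating a pair of closely related cell classes
#'   among otherwise distinct ones; remaining classes have disjoint
#'   grammars.
#' @param seed Integer master seed.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_classes = 3L, peaks_per_class = 500L,
                           region_width = 301L, genome_length = 2e6,
                           background_gc = 0.41, motifs_per_class = 2L,
                           motif_length = 8L, insertions_per_peak = c(2L, 5L),
                           shared_fraction = 0.1, grammar_overlap = 1L,
                           seed = 1L) {
  if (shared_fraction < 0 || shared_fraction >= 1) abort("shared_fraction must be in [0, 1)")
  if (motif_length >= region_width) abort("motif_length must be below region_width")
  if (region_width %% 2 == 0) abort("region_width must be odd (summit-centered)")
  if (genome_length < n_classes * peaks_per_class * region_width * 3)
    abort("genome_length too small: need at least 3x the total peak footprint")
  if (n_classes < 2) grammar_overlap <- 0L
  if (grammar_overlap < 0 || grammar_overlap > motifs_per_class)
    abort("grammar_overlap must be between 0 and motifs_per_class")
  structure(list(
    n_classes = as.integer(n_classes), peaks_per_class = as.integer(peaks_per_class),
    region_width = as.integer(region_width), genome_length = as.integer(genome_length),
    background_gc = background_gc, motifs_per_class = as.integer(motifs_per_class),
    motif_length = as.integer(motif_length),
    insertions_per_peak = as.integer(insertions_per_peak),
    shared_fraction = shared_fraction,
    grammar_overlap = as.integer(grammar_overlap), seed = as.integer(seed)
  ), class = "synthetic_spec")
}

class_labels <- function(spec) paste0("class", LETTERS[seq_len(spec$n_classes)])

#' Generate sharp, mutually distinct motif PFMs
#'
#' One grammar of `motifs_per_class` motifs per class plus one shared
#' housekeeping motif; when `grammar_overlap > 0` the first two
#' classes share that many motifs (the `class` field then lists both,
#' separated by `;`).  Consensi are rejection-sampled to pairwise
#' Hamming distance of at least half the motif length; per-column
#' consensus probabilities are drawn in \[0.80, 0.95\] (roughly >= 1
#' bit of information per position).
#'
#' @param spec A [synthetic_spec()].
#' @return Motif tibble (`motif_id`, `motif_name`, `class`, `pfm`,
#'   `consensus`); the housekeeping motif has class `"universal"`.
#' @export
make_motif_set <- function(spec) {
  if (spec$motif_length < 6) abort("motif_length must be at least 6")
  len <- spec$motif_length
  n_total <- spec$n_classes * spec$motifs_per_class - spec$grammar_overlap + 1L
  min_dist <- ceiling(len / 2)
  # consensi are GC-balanced (within len/8 of half the positions) so
  # planted peaks stay GC-comparable to background and the models must
  # learn grammar, not base composition
  gc_lo <- ceiling(len / 2 - len / 8); gc_hi <- floor(len / 2 + len / 8)
  with_seed(spec$seed, {
    consensi <- character(0)
    tries <- 0L
    while (length(consensi) < n_total) {
      cand <- paste(sample(DNA_BASES, len, TRUE), collapse = "")
      ngc <- stringr::str_count(cand, "[GC]")
      if (ngc < gc_lo || ngc > gc_hi) { tries <- tries + 1L; next }
      ok <- all(vapply(consensi, function(x) {
        a <- strsplit(cand, "")[[1]]; b <- strsplit(x, "")[[1]]
        min(sum(a != b), sum(a != rev(chartr("ACGT", "TGCA", b))))
      }, numeric(1)) >= min_dist)
      if (ok) consensi <- c(consensi, cand)
      tries <- tries + 1L
      if (tries > 200L * n_total)
        abort("could not sample mutually distinct consensi; lower motifs_per_class or raise motif_length")
    }
    pfms <- purrr::map(consensi, function(cons) {
      idx <- match(strsplit(cons, "")[[1]], DNA_BASES)
      p_major <- runif(len, 0.80, 0.95)
      mat <- vapply(seq_len(len), function(j) {
        p <- rep((1 - p_major[j]) / 3, 4)
        p[idx[j]] <- p_major[j]
        round(p * 400)
      }, numeric(4))
      rownames(mat) <- DNA_BASES
      mat
    })
  })
  # class 1 gets motifs 1..m; class 2 starts m - overlap + 1 (sharing
  # the tail of class 1's grammar); later classes are disjoint
  classes <- class_labels(spec)
  m <- spec$motifs_per_class
  assignment <- rep(list(character(0)), n_total)
  offset <- 0L
  for (i in seq_len(spec$n_classes)) {
    start <- if (i == 2) m - spec$grammar_overlap else offset
    idx <- (start + 1L):(start + m)
    for (j in idx) assignment[[j]] <- c(assignment[[j]], classes[i])
    offset <- max(offset, start + m)
  }
  assignment[[n_total]] <- "universal"
  cls <- vapply(assignment, paste, "", collapse = ";")
  tibble(
    motif_id = sprintf("SYN%02d", seq_len(n_total)),
    motif_name = ifelse(cls == "universal", "TF_HK",
                        paste0("TF_", gsub("class|;", "", cls), "_", seq_len(n_total))),
    class = cls, pfm = pfms, consensus = consensi
  )
}

# rows of the motif tibble whose (possibly multi-)class field contains cl
motif_rows_for_class <- function(motifs, cl) {
  which(vapply(strsplit(motifs$class, ";"), function(v) cl %in% v, TRUE))
}

# sample an instance sequence from a PFM's column distributions
sample_pfm_instance <- function(pfm) {
  probs <- sweep(pfm, 2, colSums(pfm), "/")
  paste(apply(probs, 2, function(p) sample(DNA_BASES, 1, prob = p)), collapse = "")
}

#' Simulate a genome with multi-class peak sets and planted grammars
#'
#' Lays out non-overlapping peak slots over an i.i.d. background
#' genome, plants each class's motif instances in its private peaks
#' and a housekeeping motif in the shared universal peaks, and emits
#' narrowPeak-style peak calls with summit offsets and scores
#' decreasing with peak rank.
#'
#' @param spec A [synthetic_spec()].
#' @param motifs Motif tibble from [make_motif_set()] (regenerated
#'   from `spec` when omitted).
#' @return List with `genome` (named character vector, 2 contigs),
#'   `peaks` (raw narrowPeak-style tibble with `class`), `motifs`, and
#'   `truth` (planted `instances` tibble, `grammar` map, and reporter
#'   generative parameters `beta`).
#' @export
simulate_genome_and_peaks <- function(spec, motifs = make_motif_set(spec)) {
  w <- spec$region_width
  half <- (w - 1L) %/% 2L
  classes <- class_labels(spec)
  n_univ <- floor(spec$shared_fraction * spec$peaks_per_class)
  n_priv <- spec$peaks_per_class - n_univ
  n_slots_needed <- n_univ + spec$n_classes * n_priv

  chrom_len <- as.integer(spec$genome_length %/% 2)
  chroms <- c(chr1 = chrom_len, chr2 = chrom_len)
  step <- w + ceiling(w / 2)
  slots <- purrr::imap_dfr(as.list(chroms), function(len, chrom) {
    starts <- seq.int(ceiling(w / 2), len - w - ceiling(w / 2), by = step)
    tibble(chrom = chrom, start = as.integer(starts))
  })
  if (nrow(slots) < n_slots_needed) abort("slot exhaustion: genome too small for the requested peaks")

  with_seed(spec$seed + 1L, {
    base_p <- c((1 - spec$background_gc) / 2, spec$background_gc / 2,
                spec$background_gc / 2, (1 - spec$background_gc) / 2)
    genome_chars <- purrr::map(as.list(chroms), function(len)
      sample(DNA_BASES, len, TRUE, prob = base_p))

    slots <- slots[sample.int(nrow(slots), n_slots_needed), , drop = FALSE]
    slot_class <- c(rep("universal", n_univ), rep(classes, each = n_priv))

    plant <- function(chrom, region_start, offset, motif_row) {
      inst <- sample_pfm_instance(motifs$pfm[[motif_row]])
      strand <- sample(c("+", "-"), 1)
      planted <- if (strand == "-") reverse_complement(inst) else inst
      genome_chars[[chrom]][(region_start + offset + 1):(region_start + offset + spec$motif_length)] <<-
        strsplit(planted, "")[[1]]
      tibble(chrom = chrom, region_start = region_start, offset = offset,
             strand = strand, motif_id = motifs$motif_id[motif_row])
    }

    instances <- purrr::pmap_dfr(
      list(slots$chrom, slots$start, slot_class),
      function(chrom, start, cls) {
        rows <- motif_rows_for_class(motifs, cls)
        n_ins <- if (cls == "universal") 2L else
          sample(seq(spec$insertions_per_peak[1], spec$insertions_per_peak[2]), 1L)
        # choose disjoint offsets first (bounded retries), then write
        used <- integer(0)
        placed <- tibble()
        for (i in seq_len(n_ins)) {
          offset <- NA_integer_
          for (try in 1:50) {
            cand <- sample.int(w - spec$motif_length + 1L, 1L) - 1L
            if (!any(abs(cand - used) < spec$motif_length)) { offset <- cand; break }
          }
          if (is.na(offset)) next
          used <- c(used, offset)
          placed <- bind_rows(placed, plant(chrom, start, offset, sample(rows, 1L)))
        }
        mutate(placed, class = cls)
      })

    genome <- vapply(genome_chars, paste, "", collapse = "")

    # raw narrowPeak-style calls: ragged intervals around each summit,
    # scores decreasing with peak index within each class
    peak_rows <- tibble(chrom = slots$chrom, region_start = slots$start,
                        slot_class = slot_class)
    peaks <- purrr::map_dfr(classes, function(cl) {
      mine <- filter(peak_rows, .data$slot_class %in% c(cl, "universal"))
      n <- nrow(mine)
      ext_l <- sample(100:250, n, TRUE)
      ext_r <- sample(100:250, n, TRUE)
      summit <- mine$region_start + half
      tibble(
        chrom = mine$chrom,
        start = pmax(0L, summit - ext_l),
        end = summit + ext_r + 1L,
        name = paste0(cl, "_peak", seq_len(n)),
        score = sort(round(runif(n, 10, 1000), 2), decreasing = TRUE),
        strand = ".",
        summit = summit,
        class = cl
      )
    })
  })

  priv <- motifs[motifs$class != "universal", ]
  grammar <- setNames(purrr::map(classes, function(cl)
    priv$motif_id[motif_rows_for_class(priv, cl)]), classes)
  beta <- setNames(rep(3, nrow(motifs)), motifs$motif_id)
  list(genome = genome, peaks = peaks, motifs = motifs,
       truth = list(instances = instances, grammar = grammar, beta = beta,
                    region_width = w))
}

#' Simulate a reporter assay over variants of one construct
#'
#' The generative model is linear in motif content: a class's
#' expression is the sum over its grammar of `beta[motif] * h`, where
#' `h` is the best PWM log-odds hit fraction of that motif in the
#' construct.  Binding is thresholded at `hit_floor` (the same 0.8
#' criterion the motif scanner uses): a motif contributes only when
#' the reference construct carries a qualifying site, and hit
#' fractions below the floor count as zero binding.  Hence a class
#' whose grammar has no site in the reference emits pure noise, a
#' variant outside every site leaves expression unchanged exactly,
#' and deleting a site changes expression by `-beta * h` of that
#' site.  Measurements average `n_reps` replicates with Gaussian
#' noise; the reported change is variant minus reference.
#'
#' @param construct Reference construct sequence.
#' @param variants Tibble with `id`, `pos` (0-based within the
#'   construct), `ref`, `alt`.
#' @param motifs Motif tibble.
#' @param truth Ground-truth list from [simulate_genome_and_peaks()]
#'   (used for `grammar` and `beta`).
#' @param classes Cell classes to emit (default: all grammar classes).
#' @param n_reps Replicates per measurement (default 5).
#' @param noise_sd Gaussian noise SD per replicate (default 0.2 assay
#'   units).
#' @param hit_floor Minimum hit fraction that counts as binding
#'   (default 0.8, matching the motif scanner's hit threshold).
#' @param seed Integer seed.
#' @return MPRA tibble: `variant_id`, `cell_class`,
#'   `expression_change`, `reference_expression`.
#' @export
simulate_mpra <- function(construct, variants, motifs, truth,
                          classes = names(truth$grammar), n_reps = 5L,
                          noise_sd = 0.2, hit_floor = 0.8, seed = 1L) {
  hit_frac <- function(motif_row, seq) {
    pwm <- pwm_logodds(motifs$pfm[[motif_row]])
    hits <- cpp_pwm_scan(seq, pwm, -1e9)
    if (nrow(hits) == 0) return(0)
    max(hits$score) / pwm_max_score(pwm)
  }
  # motifs only act through sites present in the reference construct
  ref_site <- vapply(seq_len(nrow(motifs)), function(i)
    hit_frac(i, construct) >= hit_floor, logical(1))
  names(ref_site) <- motifs$motif_id
  expr_true <- function(cl, seq) {
    ids <- truth$grammar[[cl]]
    if (is.null(ids)) return(0)
    sum(vapply(ids, function(m) {
      if (!ref_site[[m]]) return(0)
      h <- hit_frac(which(motifs$motif_id == m), seq)
      if (h < hit_floor) 0 else truth$beta[[m]] * h
    }, numeric(1)))
  }
  with_seed(seed, {
    out <- purrr::map_dfr(classes, function(cl) {
      ref_meas <- expr_true(cl, construct) +
        if (noise_sd > 0) mean(rnorm(n_reps, 0, noise_sd)) else 0
      purrr::pmap_dfr(variants[c("id", "pos", "ref", "alt")],
                      function(id, pos, ref, alt) {
        alt_seq <- apply_variant(construct, pos, ref, alt)
        meas <- expr_true(cl, alt_seq) +
          if (noise_sd > 0) mean(rnorm(n_reps, 0, noise_sd)) else 0
        tibble(variant_id = id, cell_class = cl,
               expression_change = meas - ref_meas,
               reference_expression = ref_meas)
      })
    })
  })
  out
}

#' Build a labelled SNV panel over planted and background positions
#'
#' SNVs are split between the central core of planted motif instances
#' and background positions at least 25 bp away from any instance,
#' with a ground-truth `category` column for evaluation.
#'
#' @param sim Output of [simulate_genome_and_peaks()].
#' @param n_in_motif,n_background Number of SNVs per category.
#' @param classes Restrict in-motif picks to these classes' instances
#'   (default: all private classes).
#' @param seed Integer seed.
#' @return Variant tibble (`id`, `chrom`, `pos`, `ref`, `alt`,
#'   `category`, `class`), positions 0-based.
#' @export
make_variant_panel <- function(sim, n_in_motif = 20L, n_background = 20L,
                               classes = NULL, seed = 1L) {
  inst <- sim$truth$instances
  if (!is.null(classes)) inst <- filter(inst, .data$class %in% classes)
  if (nrow(inst) < n_in_motif) abort("not enough planted motif positions for the panel")
  w <- sim$truth$region_width
  mlen <- nchar(sim$motifs$consensus[1])
  with_seed(seed, {
    picked <- inst[sample.int(nrow(inst), n_in_motif), , drop = FALSE]
    core <- picked$region_start + picked$offset + mlen %/% 2L
    in_motif <- tibble(chrom = picked$chrom, pos = core,
                       category = "in_motif", class = picked$class)

    regions <- distinct(inst, .data$chrom, .data$region_start, .data$class)
    bg <- tibble()
    while (nrow(bg) < n_background) {
      r <- regions[sample.int(nrow(regions), 1L), ]
      p <- r$region_start + sample.int(w, 1L) - 1L
      near <- filter(inst, .data$chrom == r$chrom,
                     abs(p - (.data$region_start + .data$offset + mlen %/% 2L)) < 25 + mlen)
      if (nrow(near) == 0)
        bg <- bind_rows(bg, tibble(chrom = r$chrom, pos = p,
                                   category = "background", class = r$class))
    }
    panel <- bind_rows(in_motif, bg)
    panel$ref <- genome_subseq(sim$genome, panel$chrom, panel$pos, panel$pos + 1L)
    panel$alt <- vapply(panel$ref, function(b) sample(setdiff(DNA_BASES, b), 1L), "")
  })
  panel |>
    mutate(id = paste0("var", dplyr::row_number()), .before = 1) |>
    select("id", "chrom", "pos", "ref", "alt", "category", "class")
}

#' Write a synthetic study to disk in standard formats
#'
#' Emits the genome FASTA, one narrowPeak file per class, the JASPAR
#' PFM file, the TF whitelist and a ground-truth JSON.
#'
#' @param sim Output of [simulate_genome_and_peaks()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_synthetic_study <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(sim$genome, file.path(dir, "genome.fa"))
  for (cl in unique(sim$peaks$class)) {
    df <- filter(sim$peaks, .data$class == cl)
    out <- tibble(chrom = df$chrom, start = df$start, end = df$end,
                  name = df$name, score = df$score, strand = df$strand,
                  signal = df$score, p = -1, q = -1,
                  summit_offset = df$summit - df$start)
    readr::write_tsv(out, file.path(dir, paste0(cl, ".narrowPeak")), col_names = FALSE)
  }
  write_jaspar_pfm(sim$motifs, file.path(dir, "motifs.jaspar"))
  readr::write_lines(unique(sim$motifs$motif_name), file.path(dir, "whitelist.txt"))
  truth <- sim$truth
  truth$instances <- as.list(truth$instances)
  jsonlite::write_json(truth, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
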
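# End-to-end orchestration: curation -> training/evaluation -> VIP
# products, mirroring the study workflow.  A config (list or YAML
# file) names inputs and thresholds; every output file starts with a
# provenance comment (package version, seed, config hash) and all
# randomness flows from config$seed, so reruns are byte-identical.

#' Assemble and validate a pipeline configuration
#'
#' @param genome Genome FASTA path, or a named character vector.
#' @param peaks Named list of per-class peak-file paths, or a region
#'   tibble with a `class` column.
#' @param motifs JASPAR PFM path, or a motif tibble.
#' @param whitelist Optional expressed-TF whitelist (path or character
#'   vector).
#' @param variants Optional variant table (path or tibble).
#' @param mpra Optional MPRA table (path or tibble).
#' @param class_map Optional named vector mapping model labels to MPRA
#'   cell classes (defaults to identity on model labels).
#' @param params [gkm_params()].
#' @param flank Summit extension (bp, default 150).
#' @param top_n Top peaks kept per class (default 25000).
#' @param train_fraction Training fraction (default 0.8).
#' @param min_overlap_bp Overlap rule for universality and
#'   cross-filtering (default 1).
#' @param gc_bin_width GC-matching bin width (default 0.05).
#' @param vocab_fraction Vocabulary fraction (default 0.01).
#' @param threshold_frac PWM hit threshold (default 0.8).
#' @param profile_window Motif profile flank (default 30).
#' @param flank_context Variant scoring context half-width (default 150).
#' @param n_saturation_regions Outgroup regions per class to saturate
#'   (default 20).
#' @param seed Master seed.
#' @param outdir Optional output directory; when set, every stage
#'   writes its products there.
#' @return A `crevip_config` list.
#' @export
crevip_config <- function(genome, peaks, motifs, whitelist = NULL,
                          variants = NULL, mpra = NULL, class_map = NULL,
                          params = gkm_params(), flank = 150L, top_n = 25000L,
                          train_fraction = 0.8, min_overlap_bp = 1L,
                          gc_bin_width = 0.05, vocab_fraction = 0.01,
                          threshold_frac = 0.8, profile_window = 30L,
                          flank_context = 150L, n_saturation_regions = 20L,
                          seed = 1L, outdir = NULL) {
  for (p in c(if (is_path(genome)) genome,
              if (is.list(peaks) && !is.data.frame(peaks)) unlist(peaks),
              if (is_path(motifs)) motifs)) {
    if (!file.exists(p)) abort(paste0("input path does not exist: ", p))
  }
  structure(list(
    genome = genome, peaks = peaks, motifs = motifs, whitelist = whitelist,
    variants = variants, mpra = mpra, class_map = class_map, params = params,
    flank = as.integer(flank), top_n = as.integer(top_n),
    train_fraction = train_fraction, min_overlap_bp = as.integer(min_overlap_bp),
    gc_bin_width = gc_bin_width, vocab_fraction = vocab_fraction,
    threshold_frac = threshold_frac, profile_window = as.integer(profile_window),
    flank_context = as.integer(flank_context),
    n_saturation_regions = as.integer(n_saturation_regions),
    seed = as.integer(seed), outdir = outdir
  ), class = "crevip_config")
}

#' Read a pipeline configuration from YAML
#'
#' Path-valued keys are interpreted relative to the YAML file's
#' directory.
#'
#' @param path YAML file.
#' @return A `crevip_config`.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(path)
  rel <- function(p) if (is.null(p)) NULL else
    ifelse(file.exists(p) | grepl("^/", p), p, file.path(base, p))
  pk <- y$peaks
  if (!is.null(pk)) pk <- purrr::map(pk, rel)
  pr <- do.call(gkm_params, c(y$params %||% list()))
  crevip_config(
    genome = rel(y$genome), peaks = pk, motifs = rel(y$motifs),
    whitelist = rel(y$whitelist), variants = rel(y$variants),
    mpra = rel(y$mpra), class_map = unlist(y$class_map), params = pr,
    flank = y$flank %||% 150L, top_n = y$top_n %||% 25000L,
    train_fraction = y$train_fraction %||% 0.8,
    min_overlap_bp = y$min_overlap_bp %||% 1L,
    gc_bin_width = y$gc_bin_width %||% 0.05,
    vocab_fraction = y$vocab_fraction %||% 0.01,
    threshold_frac = y$threshold_frac %||% 0.8,
    profile_window = y$profile_window %||% 30L,
    flank_context = y$flank_context %||% 150L,
    n_saturation_regions = y$n_saturation_regions %||% 20L,
    seed = y$seed %||% 1L, outdir = y$outdir
  )
}

config_hash <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(config[setdiff(names(config), "outdir")], tmp)
  unname(tools::md5sum(tmp))
}

provenance_line <- function(config) {
  sprintf("# crevip %s; seed=%d; config=%s",
          as.character(utils::packageVersion("crevip")),
          config$seed, config_hash(config))
}

write_tsv_prov <- function(df, path, config) {
  readr::write_lines(provenance_line(config), path)
  readr::write_tsv(df, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

# a bare unnamed length-1 string is a file path; named vectors and
# tibbles are in-memory inputs
is_path <- function(x) {
  is.character(x) && length(x) == 1 && is.null(names(x)) && nchar(x) < 500
}

load_inputs <- function(config) {
  genome <- if (is_path(config$genome)) read_genome_fasta(config$genome) else config$genome
  peaks <- if (is.data.frame(config$peaks)) config$peaks else {
    purrr::imap_dfr(config$peaks, function(p, cl)
      mutate(read_narrowpeak(p), class = cl))
  }
  motifs <- if (is_path(config$motifs)) read_jaspar_pfm(config$motifs) else config$motifs
  whitelist <- if (is_path(config$whitelist) && file.exists(config$whitelist)) {
    readr::read_lines(config$whitelist)
  } else config$whitelist
  list(genome = genome, peaks = peaks, motifs = motifs, whitelist = whitelist)
}

#' Curate training, outgroup and negative sets for every class
#'
#' Runs summit extension, universal-region removal, top-N selection,
#' the train/outgroup split, cross-class outgroup filtering and
#' GC-matched negative sampling, and assembles a per-class manifest.
#'
#' @param config A `crevip_config`.
#' @return List with `sets` (tibble: `class`, `partition` in
#'   train/outgroup/negative, regions with sequences), `universal`
#'   (removed regions) and `manifest` (per class and partition: count
#'   and mean GC).
#' @export
run_prepare <- function(config) {
  inp <- load_inputs(config)
  extended <- extend_summits(inp$peaks, inp$genome, config$flank)
  ru <- remove_universal(extended, config$min_overlap_bp)
  topped <- select_top(ru$filtered, config$top_n)
  split <- split_train_outgroup(topped, config$train_fraction, config$seed)
  uniform <- build_uniform_testset(split, config$min_overlap_bp)
  split <- bind_rows(filter(split, .data$partition == "train"), uniform)
  pos_seq <- region_sequences(split, inp$genome)
  classes <- sort(unique(split$class))
  negatives <- purrr::map_dfr(seq_along(classes), function(i) {
    cl <- classes[i]
    pos <- filter(split, .data$class == cl, .data$partition == "train")
    neg <- sample_gc_matched_negatives(pos, inp$genome, extended,
                                       config$gc_bin_width, config$seed + i)
    mutate(neg, class = cl, partition = "negative", summit = NA_integer_)
  })
  sets <- bind_rows(mutate(pos_seq, gc = gc_content(.data$seq)), negatives)
  manifest <- sets |>
    group_by(.data$class, .data$partition) |>
    summarise(n_regions = dplyr::n(), mean_gc = mean(.data$gc), .groups = "drop")
  if (!is.null(config$outdir)) {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    for (cl in classes) for (part in c("train", "outgroup", "negative")) {
      df <- filter(sets, .data$class == cl, .data$partition == part)
      stem <- file.path(config$outdir, paste0(cl, "_", part))
      write_bed(df, paste0(stem, ".bed"))
      write_fasta(setNames(df$seq, df$name), paste0(stem, ".fa"))
    }
    write_tsv_prov(manifest, file.path(config$outdir, "manifest.tsv"), config)
  }
  list(sets = sets, universal = ru$universal, manifest = manifest)
}

#' Train and evaluate one model per class
#'
#' Computes each class's kernel matrix once, runs the seeded five-fold
#' cross-validation on it, trains the final model, extracts the full
#' l-mer weight table, and scores every class's uniform test set with
#' every model.
#'
#' @param config A `crevip_config`.
#' @param prepared Output of [run_prepare()].
#' @return List with `models`, `cv`, `weights` (named per class) and
#'   `matrix` (a `class_score_matrix`).
#' @export
run_train_and_evaluate <- function(config, prepared) {
  sets <- prepared$sets
  classes <- sort(unique(sets$class))
  fitted <- purrr::map(classes, function(cl) {
    pos <- filter(sets, .data$class == cl, .data$partition == "train")$seq
    if (length(pos) == 0) abort(paste0("empty training set for class ", cl))
    neg <- filter(sets, .data$class == cl, .data$partition == "negative")$seq
    gram <- gkm_kernel_matrix(c(pos, neg), config$params, raw = TRUE)
    cv <- gkm_cv(pos, neg, config$params, folds = 5L, seed = config$seed,
                 class_label = cl, gram = gram)
    model <- gkm_train(pos, neg, config$params, class_label = cl, gram = gram)
    list(model = model, cv = cv, weights = extract_kmer_weights(model))
  })
  names(fitted) <- classes
  models <- purrr::map(fitted, "model")
  cv <- purrr::map(fitted, "cv")
  weights <- purrr::map(fitted, "weights")
  testsets <- filter(sets, .data$partition == "outgroup")
  mat <- cross_class_score_matrix(models, testsets)
  if (!is.null(config$outdir)) {
    for (cl in classes) {
      write_gkm_model(models[[cl]], file.path(config$outdir, paste0(cl, "_model.json")))
      write_kmer_weights(weights[[cl]], file.path(config$outdir, paste0(cl, "_weights.tsv.gz")))
      write_tsv_prov(cv[[cl]]$roc, file.path(config$outdir, paste0(cl, "_cv_roc.tsv")), config)
    }
    write_tsv_prov(purrr::map_dfr(cv, glance),
                   file.path(config$outdir, "cv_summary.tsv"), config)
    write_tsv_prov(tidy(mat), file.path(config$outdir, "cross_class_matrix.tsv"), config)
  }
  list(models = models, cv = cv, weights = weights, matrix = mat)
}

#' Vocabulary, saturation, profile, variant and MPRA products
#'
#' Ranks each model's vocabulary and computes motif-count z-scores
#' across models; saturates a seeded sample of each class's outgroup
#' regions and emits summed VIP tracks; builds motif-centered VIP
#' profiles; scores the external variant table when supplied; joins
#' against MPRA measurements when supplied (skipped with a message
#' otherwise).
#'
#' @param config A `crevip_config`.
#' @param prepared Output of [run_prepare()].
#' @param trained Output of [run_train_and_evaluate()].
#' @return List with `vocab_counts`, `zscores`, `vip_tables`,
#'   `tracks`, `profiles`, `scored_variants`, `mpra`.
#' @export
run_vip <- function(config, prepared, trained) {
  inp <- load_inputs(config)
  classes <- names(trained$weights)
  motifs <- inp$motifs

  vocab_counts <- purrr::map_dfr(classes, function(cl) {
    top <- top_fraction(rank_vocabulary(trained$weights[[cl]]), config$vocab_fraction)
    mutate(count_motifs_in_top_vocab(top, motifs, inp$whitelist,
                                     config$threshold_frac), class = cl)
  })
  zscores <- motif_zscores(vocab_counts)

  outgroup <- filter(prepared$sets, .data$partition == "outgroup")
  sat_regions <- with_seed(config$seed, {
    outgroup |> group_by(.data$class) |>
      slice_sample(n = config$n_saturation_regions) |> ungroup()
  })
  vip_tables <- purrr::map(classes, function(cl) {
    purrr::map(seq_len(nrow(sat_regions)), function(i)
      saturation_mutagenesis(trained$weights[[cl]], sat_regions[i, ]))
  })
  names(vip_tables) <- classes
  tracks <- purrr::map(vip_tables, function(tabs)
    bind_rows(purrr::map(tabs, summed_vip_track)) |>
      select("chrom", pos = "genome_pos", "value"))

  occurrences <- scan_motif_occurrences(sat_regions, inp$genome, motifs,
                                        config$threshold_frac)
  profiles <- purrr::map_dfr(classes, function(cl) {
    if (nrow(occurrences) == 0) return(tibble())
    mutate(motif_vip_profile(vip_tables[[cl]], occurrences,
                             config$profile_window), model = cl)
  })

  scored_variants <- NULL
  if (!is.null(config$variants)) {
    variants <- if (is.character(config$variants))
      read_variant_table(config$variants, genome = inp$genome) else config$variants
    scored_variants <- score_variant_table(trained$weights, variants, inp$genome,
                                           config$flank_context, motifs,
                                           config$threshold_frac)
  }
  mpra_out <- NULL
  if (!is.null(config$mpra) && !is.null(scored_variants)) {
    mpra <- if (is.character(config$mpra)) read_mpra_table(config$mpra) else config$mpra
    class_map <- config$class_map %||% setNames(classes, classes)
    vip_long <- scored_variants |>
      select("id", dplyr::starts_with("vip_")) |>
      tidyr::pivot_longer(dplyr::starts_with("vip_"), names_to = "model",
                          values_to = "vip", names_prefix = "vip_") |>
      rename(variant_id = "id")
    joined <- join_vip_mpra(vip_long, mpra, class_map)
    mpra_out <- list(joined = joined, correlations = correlation_by_class(joined))
  } else if (!is.null(config$mpra)) {
    inform("run_vip: MPRA supplied without variants; MPRA stage skipped")
  } else {
    inform("run_vip: no MPRA file supplied; MPRA stage skipped")
  }

  if (!is.null(config$outdir)) {
    write_tsv_prov(zscores, file.path(config$outdir, "motif_zscores.tsv"), config)
    for (cl in classes) {
      sat <- bind_rows(vip_tables[[cl]])
      write_tsv_prov(sat, file.path(config$outdir, paste0(cl, "_saturation.tsv")), config)
      write_bedgraph(tracks[[cl]], file.path(config$outdir, paste0(cl, "_summed_vip.bedGraph")))
    }
    if (nrow(profiles) > 0)
      write_tsv_prov(profiles, file.path(config$outdir, "motif_profiles.tsv"), config)
    if (!is.null(scored_variants))
      write_tsv_prov(scored_variants |> select(-"ref_context", -"alt_context"),
                     file.path(config$outdir, "scored_variants.tsv"), config)
    if (!is.null(mpra_out))
      write_tsv_prov(mpra_out$correlations,
                     file.path(config$outdir, "mpra_correlations.tsv"), config)
  }
  list(vocab_counts = vocab_counts, zscores = zscores, vip_tables = vip_tables,
       tracks = tracks, profiles = profiles, scored_variants = scored_variants,
       mpra = mpra_out)
}
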
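# The standing benchmark study at full scale: three classes of 500
# peaks (301 bp), default gkm-SVM hyperparameters (l = 11, k = 7),
# curated and trained through the pipeline.  Built once per session.

get_benchmark <- function() cached("benchmark", function() {
  spec <- synthetic_spec(seed = 1)
  sim <- simulate_genome_and_peaks(spec)
  cfg <- crevip_config(genome = sim$genome, peaks = sim$peaks,
                       motifs = sim$motifs, params = gkm_params(),
                       seed = 1, n_saturation_regions = 20)
  prep <- suppressMessages(run_prepare(cfg))
  trained <- suppressMessages(run_train_and_evaluate(cfg, prep))
  list(spec = spec, sim = sim, cfg = cfg, prep = prep, trained = trained)
})

# all SNVs of a reporter construct within +/- `window` bp of a planted
# motif instance, ordered by position, capped at `n`
construct_snv_panel <- function(construct, inst_start, motif_len, window, n) {
  lo <- max(0L, inst_start - window)
  hi <- min(nchar(construct) - 1L, inst_start + motif_len - 1L + window)
  refs <- strsplit(substr(construct, lo + 1, hi + 1), "")[[1]]
  panel <- tidyr::crossing(pos = lo:hi, alt = c("A", "C", "G", "T")) |>
    dplyr::mutate(ref = refs[.data$pos - lo + 1]) |>
    dplyr::filter(.data$ref != .data$alt) |>
    dplyr::mutate(id = paste0("s", dplyr::row_number()))
  head(panel, n)
}

# reporter construct carrying exactly one instance (the consensus) of
# one class's private motif on background at the study GC level
make_reporter_construct <- function(sim, motif_id, len = 301L, at = 140L, seed = 5L) {
  cons <- sim$motifs$consensus[sim$motifs$motif_id == motif_id]
  withr::with_seed(seed, bg <- random_dna(1, len, gc = 0.41))
  list(seq = paste0(substr(bg, 1, at), cons,
                    substr(bg, at + nchar(cons) + 1, len)),
       inst_start = at, motif_len = nchar(cons))
}
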
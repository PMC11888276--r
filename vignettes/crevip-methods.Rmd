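---
title: "Methods: gapped k-mer models of cell-class regulatory grammar and variant impact scoring"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gapped k-mer models and variant impact scoring}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its methods: the models and
procedures it implements, the tunable parameters and their defaults,
what the synthetic-data generator does and does not emulate, the
numerical choices, and the known limitations. Nothing here states an
empirical result that the test suite or `scripts/acceptance.R` does
not itself compute.

## The classification model

Each cell class is modeled by a binary classifier separating its
accessible candidate CREs from inaccessible, GC-matched background
sequence. Sequences are compared through the gapped k-mer kernel: a
sequence is implicitly represented by the count vector of its gapped
k-mers — length-`l` windows with `k` informative positions and
`l − k` wildcards — and the raw kernel is the inner product of two
such vectors. It is computed without materializing the feature space:
every pair of l-mers, one from each sequence, differing at `m`
positions contributes `choose(l − m, k)` shared gapped k-mers.

Parameters (all in `gkm_params()`):

- `l = 11` (word length, bp). The vocabulary scored downstream is all
  `4^11` 11-mers, so `l` fixes both the kernel and the weight-table
  resolution.
- `k = 7` (informative positions). Around 60–65% informative content
  tolerates the degenerate positions typical of TF binding sites.
- `d = l − k` (mismatch cap). The default is deliberately untruncated:
  with `d = l − k` the closed form above is exactly the gapped k-mer
  inner product, which is what makes (a) the kernel testable against
  brute-force feature enumeration, (b) fast Gram computation by
  per-pattern bucket counting, and (c) exact scoring of all `4^l`
  l-mers through per-pattern lookup tables. A truncated `d < l − k`
  is supported in the pairwise kernel path for experimentation, but
  the fast scoring machinery requires the untruncated kernel.
- `both_strands = TRUE`. The kernel counts the reverse complement of
  one argument as well, making decision values and k-mer weights
  strand-symmetric — a variant scored on either strand gets the same
  VIP.
- `C = 1` (soft-margin cost) on the *normalized* kernel
  `K(x,y)/sqrt(K(x,x) K(y,y))`, whose diagonal is 1; a jitter of 1e-8
  is added to the diagonal before solving.

The SVM itself is solved by `kernlab::ksvm` on the precomputed
normalized Gram matrix; the package stores the support sequences and
dual coefficients and computes all decision values through its own
lookup-table scorer, so serialized models are self-contained. At the
benchmark scale (hundreds to a few thousand training sequences) the
O(n²) Gram matrix is unproblematic; this is the intended operating
range, not a large-scale reimplementation of approximate kernel
tricks.

### The k-mer weight table

The weight of an l-mer `u` is its decision value minus the bias,
`w(u) = Σ_i α_i K(u, sv_i)`. All `4^l` weights are computed exactly
via `choose(l, k)` position-pattern lookup tables built from the
support vectors. With both-strand counting the per-l-mer
normalization `K_raw(u,u) = C(l,k) + C(l − h, k)` (with `h` the
Hamming distance between `u` and its reverse complement) varies by
l-mer and is applied per entry, preserving
`w(u) = w(revcomp(u))` to numerical precision.

## Peak curation

The curation pipeline mirrors the standard practice for training such
models from per-class peak calls:

1. **Summit extension** (`flank = 150`): each macs2 summit becomes a
   `2·150 + 1 = 301` bp candidate CRE; peaks clipped at contig
   boundaries are dropped (not truncated) so every region has equal
   width — the kernel and saturation bookkeeping assume it.
2. **Universal-region removal**: a region overlapping (≥ 1 bp by
   default) some region of *every* other class is treated as
   housekeeping-accessible and removed before anything else; keeping
   such regions would teach every model the same grammar.
3. **Top-N selection** (`top_n = 25000`) by peak score, ties broken by
   coordinate for determinism.
4. **80/20 split** into training and outgroup partitions (seeded),
   then **cross-class filtering**: outgroup regions overlapping any
   class's training regions are removed, yielding a uniform test
   universe no model has trained on.
5. **GC-matched negatives**: candidate windows of the positive width
   are tiled at half-width steps across the genome, windows
   overlapping any accessible region or containing N are discarded,
   and negatives are sampled so the GC histogram (bins of 0.05)
   matches the positives bin for bin, 1:1 with the positive count. A
   deficit of one window in an exhausted bin is tolerated and logged;
   larger deficits are an error rather than a silent mismatch.

The 1-bp overlap rule is the most conservative exclusion; both it and
the bin width are configurable. All coordinates are 0-based half-open
internally; 1-based variant tables are converted in exactly one place
(`to_zero_based()`).

## Variant impact prediction

`delta_svm_snv()` sums `w(alt window) − w(ref window)` over the ≤ `l`
windows covering the edited base. This windowed sum *equals* the
difference of full additive sequence scores — an identity the tests
assert to 1e-9 over random weight tables — so saturation mutagenesis
of a 301 bp region costs 903 window-local updates rather than 903
rescans. Indels and multi-base edits are scored by whole-context
rescoring (`delta_svm_indel()`), matching how reporter constructs
with motif deletions are compared; no gap alignment of windows is
attempted. VIP scores are *within-model* quantities: the package
deliberately does not calibrate scores across models onto a common
scale.

Motif-centered profiles average VIP over all occurrences of a motif
(PWM hits at ≥ 80% of the maximum attainable log-odds score, both
strands, palindromic double-hits collapsed to the forward strand) at
each offset in a ±30 bp window, flipping minus-strand occurrences
into motif orientation. The ±30 bp default follows the wider of the
two presentation conventions; ±25 bp is one argument away.
Variant-table scoring uses a context window of 150 bp per side —
far more than the `l − 1 = 10` bp the additive score actually needs,
so results are invariant to context size, which the tests check.

## PWM handling

JASPAR-format PFMs are normalized with a pseudocount of 1% of each
column's total (spread equally over the four bases) and scored as
log2 odds against a uniform background. A hit requires
`score ≥ threshold_frac × max score` with `threshold_frac = 0.8`
throughout the package — vocabulary motif counting, occurrence
scanning, and the reporter simulation all share this one criterion. A
tiny slack (1e-9) keeps exact-consensus sites inside the threshold at
`threshold_frac = 1` despite floating-point rounding.

Vocabulary analysis ranks all `4^l` l-mers per model (ties broken
lexicographically), takes the top 1% (41,943 11-mers), counts PWM
hits per motif — hit counts, not k-mer counts, so one k-mer can
contribute several occurrences — optionally filters motifs by an
expressed-TF whitelist, and z-scores each motif's counts across
models (zero-SD rows get z = 0).

## The synthetic study generator

`synthetic_spec()` defines the standing benchmark: 3 cell classes ×
500 peaks, 301 bp regions on a 2 Mb two-contig genome of i.i.d. bases
at 41% GC (human-like), two sharp 8-bp motifs per class grammar with
the first two classes sharing one motif (`grammar_overlap = 1`,
emulating closely related classes such as photoreceptor subtypes), a
10% universally accessible fraction carrying a housekeeping motif,
and 2–5 motif instances planted per private peak. Instances are
*sampled* from the PFMs (per-column consensus probabilities in
0.80–0.95, ≥ 1 bit/position average information), not pasted as
consensus, so planted sites vary realistically. Consensi are
GC-balanced (GC content within `len/8` of half the positions): a
GC-skewed grammar would shift a whole class's peaks away from the
background GC level, both making GC-matched negative sampling
infeasible in the tail bins and letting models succeed on base
composition alone — the opposite of what the benchmark is meant to
test.

The planting density deserves a note. The benchmark is calibrated so
that its ground-truth separability mirrors the intended operating
regime of such models (accuracies above 0.9): an oracle classifier
that scores regions by the true planted PWMs — independent of the
gkm machinery — reaches AUROC ≈ 0.96–0.97 against the GC-matched
negatives at 2–5 instances per peak, whereas 1–3 instances cap even
the oracle near 0.89. The model-accuracy checks therefore test
whether the gkm-SVM closes the gap to a ceiling the data genuinely
supports, not whether the generator was made trivially easy:
training-set AUROCs remain meaningfully below the oracle ceiling.

The simulated reporter assay drives expression linearly in motif
content: each class's expression is `Σ β_m · h_m` over its grammar,
where `h_m` is the best PWM hit fraction of motif `m` in the (edited)
construct, thresholded at the package-wide 0.8 hit criterion and
gated on the *reference* construct carrying a qualifying site. The
gating makes the generative contract exact: classes whose grammar is
absent from the construct emit pure measurement noise; variants
outside every site change expression by exactly zero at zero noise;
deleting a site changes expression by `−β · h` of that site.
Measurements average 5 replicates of Gaussian noise (SD 0.2 assay
units).

What the generator does **not** emulate: higher-order background
structure (the genome is i.i.d., no repeats or CpG islands),
fragment-level ATAC signal or count noise (peak scores are synthetic
ranks), cooperative or saturating TF binding (expression is additive
and single-site thresholded), and cross-species conservation. Tests
passing on this benchmark demonstrate that the implementation
recovers planted structure under known conditions; they do not
certify performance on real chromatin, where signal composition and
confounders are richer.

## Problem sizes and numerical choices

The benchmark trains each class on 360 positives + 360 negatives
(after universal-region removal and the 80/20 split of 450 retained
peaks), computes one 720×720 raw Gram per class and reuses it across
the five CV folds and the final fit. Full 4^11 weight tables are
built per model; vocabulary analysis runs on the complete tables.
These sizes keep a complete run (fixture generation through all
products) in the tens of minutes on a single core while remaining
large enough for stable AUROC and enrichment estimates.

Stochastic assay-correlation checks are evaluated on the median over
5 replicate noise draws: the non-expressing-class null has
`sd(r) ≈ 1/sqrt(n) ≈ 0.07` at n = 200, so any single draw can exceed
a 0.2 bound by chance a fraction of a percent of the time; the median
makes the check a property of the method rather than of one noise
vector, without changing the bound or the conditions.

Other numerical details: kernel values are integers in raw form
(exact up to double precision ~2^53); ROC curves place one point per
distinct threshold and AUROC uses the trapezoidal rule on pooled
out-of-fold decision values (per-fold values are also reported —
pooling mixes fold-specific decision scales, which can leave pooled
AUROC slightly below per-fold values even when every fold separates
perfectly); hierarchical clustering of the cross-class matrix uses
average linkage on correlation distance and is skipped below 3 rows;
`kernlab`'s internal label coding is resolved against its own fitted
labels so positive decision values always mean "accessible-like".

## Known limitations

- The exact Gram computation is O(n²·L²/word) and intended for desk
  scale (≤ a few thousand sequences); no sampled or tree-based
  approximations are provided.
- Weight tables require `l ≤ 16` in principle and are practical to
  `l ≈ 12` (4^12 doubles ≈ 134 MB).
- The additive deltaSVM surrogate ignores epistasis between edits
  more than `l − 1` bp apart by construction, and within-window
  epistasis is only what the SVM's support expansion encodes.
- Pure deletions at a sequence's edge leave fewer than `l` covering
  windows; scores there reflect only the existing windows.
- MPRA comparison starts from summarized per-variant expression
  values; barcode-level processing is out of scope.
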
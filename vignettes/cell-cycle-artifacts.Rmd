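---
title: "Cell-cycle composition artifacts: models, corrections and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cell-cycle composition artifacts: models, corrections and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Proliferating cell populations are mixtures over cell-cycle phases, and the
mixture differs between cell types: embryonic stem cells sit mostly in S
phase while differentiated fibroblasts sit mostly in G1. Because S-phase
cells are replicating asynchronously, the fraction of cells in S phase — the
S-phase ratio, SPR — leaves systematic fingerprints in every omics layer
built on read counts:

* **Read depth / CNV calling.** A cell partway through S phase carries two
  copies of its early-replicating DNA and one copy of the rest. Pooled over
  many cells, read depth rises over early replication-timing (RT) domains
  and falls over late ones, and a threshold-based CNV caller converts the
  ramp into *pseudo-CNVs*: gains concentrated in early domains, losses in
  late ones.
* **Chromatin accessibility.** The same dosage ramp inflates S-phase peak
  calls over early domains, producing phase-specific open-chromatin regions
  (OCRs) that do not correlate with the expression of nearby genes.
* **DNA methylation.** Remethylation of nascent DNA lags replication, most
  strongly at solo-WCGW CpGs (A/T flanks, no CpG neighbour within 100 bp).
  S-phase-rich samples therefore look globally hypomethylated at those
  sites, and a pooled comparison of two populations with different SPRs
  calls spurious differentially methylated regions (DMRs).
* **Expression.** Genes whose expression tracks the cell cycle differ
  between two populations simply because the populations occupy different
  phases; a pooled ("direct") differential-expression comparison attributes
  the difference to cell identity.

`cyclegate` implements the corrective toolkit for each layer, plus a seeded
synthetic-data generator that reproduces the statistical structure the
corrections assume, so the whole pipeline is testable without sequencing
data.

# Models and procedures

## Replication-timing correction of binned depth (depthtrack)

Reads are counted in fixed windows and summarised as `log2(count / m)` with
`m` the genome-wide median. The correction stratifies windows by their
normalised covariate value — RT divided by its maximum absolute value
(keeping the sign of late domains), or the GC fraction as-is — into
fixed-width bins of the covariate (`bin_width`, default 0.01), and rescales
each window by `m / m_stratum`, where `m_stratum` is the median depth of
its stratum. Every stratum's median lands exactly on `m`, which removes any
depth trend that is a function of the covariate while leaving within-stratum
variation (true CNVs, noise) untouched.

Two numerical choices matter. First, strata with zero median pass through
unchanged with a warning rather than erroring: sparse covariate tails are
expected. Second, the corrected track keeps `m` as its reference median
rather than recomputing a pooled median: the rescaling makes `m` an exact
median of every stratum, so `m` remains a median of the pool, and keeping
it makes the correction exactly idempotent (a recomputed pooled median of an
even-sized track can drift off `m` by floating noise, which would then
rescale the whole track on a second application).

A LASSO alternative (`residual_correct`) fits an L1-penalised degree-3
polynomial of depth on the covariate and returns residual + `m`; it is the
conventional GC-style regression correction and is kept for comparison.

## CNV segmentation and enrichment (cnvseg)

The default segmenter is a deterministic run-merge: windows with
`|log2| >= 0.25` are classed gain/loss, maximal same-class runs become
segments, and segments no longer than 5 kb are dropped (strict, so a call
must span more than the minimum). A CBS-like `recursive_split` (maximal
two-sample t statistic, permutation stopping rule) is available when a
non-thresholding segmenter is wanted. Segments are annotated with the
maximum RT value over the windows they overlap; a positive score is
"earlier", otherwise "later".

The imbalance of calls across RT domains is summarised by odds-ratio-style
enrichment scores:

```
ES_gain = (n_gain_early / n_loss_early) / (n_gain / n_loss)
ES_loss = (n_loss_late  / n_gain_late)  / (n_loss / n_gain)
```

with a Haldane–Anscombe 0.5 added to all four cells of a ratio containing a
zero. Balance is tested by binomial tests within a call class and by
Fisher/chi-square tests between classes or call sets (Fisher when any
expected cell is ≤ 5).

## The SPR mixing algebra (mixsim)

Two libraries with known S-phase ratios `S_esc > S_mef` and read totals
`RC_esc`, `RC_mef` are mixed so that the mixture keeps the first library's
total and achieves a target ratio `S_ratio`:

```
x · RC_esc + y · RC_mef = RC_esc
x · S_esc · RC_esc + y · S_mef · RC_mef = S_ratio · RC_esc
```

whence `x = (S_ratio − S_mef)/(S_esc − S_mef)` and
`y = (1 − x) · RC_esc / RC_mef`. Note `x` depends only on the three S
fractions. Mixing and depth downsampling are realised as per-window binomial
thinning, which has the same distribution as read-level subsampling for any
window-count statistic while avoiding read-level storage. `spr_sweep` runs
the full loop (simulate endpoint pools → solve → mix → optionally correct →
segment → count and score) over an SPR grid; `onset_spr` reports the grid
point of maximal second difference of the segment-count curve, a heuristic
change-point summary of where pseudo-CNVs escalate.

## Phase assignment and evaluation (phasing)

Marker augmentation correlates each candidate gene's three-point per-phase
mean profile (log2 CPM+1) with a standardised one-hot template per phase;
genes whose best correlation is below 0.1 are excluded as weak (boundary
inclusive on the keep side), and base-set membership wins conflicts. The
classifier itself is deliberately transparent — per-phase mean of z-scored
log2 CPM+1 over marker genes, argmax with a fixed G1 < S < G2M tie order —
because the evaluation protocol, not the classifier, is the point:
one-vs-rest precision `TP/(TP+FP)`, sensitivity `TP/(TP+FN)`, their
harmonic-mean F1, macro-averaged, optionally over repeated 90% resamples of
the cells.

## Phase-stratified differential expression (dge)

The per-gene test is a two-part hurdle: a 1-df likelihood-ratio statistic
on detection (logistic detection ~ group, the 2×2 G-test) plus a 1-df
normal likelihood-ratio statistic on log2 CPM+1 among detected cells
(contributing only when both sides have ≥ 2 detected cells); the sum is
chi-square with as many degrees of freedom as contributing components, and
Benjamini–Hochberg corrects across genes. Significance requires fold change
≥ 2 or ≤ 0.5 (boundary inclusive) and FDR < 0.05. Fold changes are group-B
over group-A mean CPM with a 0.1 stabiliser.

*Direct comparison* pools all cells per group. *Phase comparison* runs the
test within each phase having at least 3 cells per side, then merges the
per-phase significant sets by union; genes significant in two phases with
opposite directions are flagged discordant and dropped from the merged set
(kept in provenance). Signature scores follow the control-gene-matching
scheme: genes are binned into 25 average-expression bins and each signature
gene is compared with 100 controls drawn from its own bin.

## Methylation (methyl)

CpGs are classed by their flanking bases (W = A/T, S = C/G) into WCGW,
SCGS, and a combined SCGW class covering both mixed arrangements (the two
orders are reverse complements of each other and indistinguishable for a
strand-symmetric CpG). A CpG is *solo* when no other CpG lies within 100 bp
(a neighbour at exactly 100 bp breaks the flag). The delay summary takes
per-site G1 − S level differences at sites with ≥ 5 reads per phase and
t-tests each context against zero. DMRs are called on fixed 1 kb tiles with
≥ 3 covered CpGs: counts are pooled per side, tested two-sided by Fisher's
exact test, BH-corrected, and a DMR requires a pooled difference above 30
percentage points *and* q < 0.01. Promoters are TSS − 2 kb to TSS + 500 bp
(strand-mirrored), summarised only when ≥ 10 CpGs are covered.

## Open chromatin (chromacc)

Pseudo-mix fractions solve the exact G1:S:G2M = 5:3:2 recombination: the
binding phase — the one whose reads are scarcest relative to its target
share — is kept whole and the others are thinned to match, so the achieved
ratio is exact in expectation. Peaks merge when they truly share ≥ 1 bp
(book-ended intervals stay separate). Canonical OCRs are base-pair
intersection cores across the three phases (well-defined under partial
overlaps and checkable against a brute-force coverage oracle); a phase's
specific OCRs are its peaks absent from the pseudo-mix, and
pseudo-mix-specific OCRs are pseudo-mix peaks absent from the canonical
core. Peak RT labels use the same max-overlap score as CNVs but with the
accessibility rule: > 0.25 earlier, < −0.25 later, otherwise no change.
The five regulatory groups cross an openness axis (above the 75th
percentile = More_Open, below 1 on the TPM-like openness scale =
Less_Open) with the analogous expression axis; undetermined axes fall into
`None`, so the groups partition genes. OCR–CNV overlap ratios are compared
against 1000 length-matched random placements, uniform within chromosomes
chosen proportional to length.

# The synthetic generator: what it emulates and what it does not

The generator defines the study conditions for every test in the package.

* **Genome (`make_genome`).** RT is a smooth sum of low-frequency sinusoids
  scaled to ±amplitude — domain-like alternation of early and late regions
  without modelling origin firing. GC is constructed with a controlled
  Pearson correlation to RT via an orthogonalised noise mixture.
* **Depth (`simulate_wgs_bins`).** Each S cell draws a progression
  `u ~ U(0,1)` and has copy 2 in the earliest-replicating fraction `u` of
  windows (rank-threshold model), G1 cells copy 1, G2M copy 2, spikes
  multiply copy; counts are Poisson. This reproduces the monotone RT–depth
  coupling (sample correlations ≈ 0.7 at SPR 0.55, ≈ 0 in pure G1) without
  any claim about per-cell replication kinetics.
* **Expression (`simulate_expression`).** Negative binomial counts with
  per-gene phase multipliers and group log2 fold changes, thinned by a
  logistic-in-log-mean detection model (dropout). Library composition is
  realistic only to first order: per-cell CPM normalisation is used
  throughout, so designs in which DE genes carry a large share of library
  mass shift CPM between groups — a known limitation of CPM, not of
  phasing, and the reason fixtures keep planted DE mass small.
* **Methylome (`simulate_methylome`).** G1 counts Binomial(cov,
  `base_level`); S counts Binomial(cov, `base_level · (1 − delay·s)`) with
  `s = 1` at solo and `0.5` at non-solo sites. The planted G1 − S drop is
  therefore `base_level · delay · s`, and recovery tests target that
  quantity. Site geometry (isolated solo sites; non-solo pairs 50 bp apart)
  is constructed to agree exactly with the nearest-neighbour solo flag.
* **Peaks (`simulate_peaks`).** A shared backbone identical across phases
  (same seed stream) plus phase-specific peaks; S-specific peaks are placed
  with probability ∝ `exp(bias · RT)`.

Defaults encode the reference conditions: endpoint S fractions 0.55/0.20,
compositions (0.03, 0.88, 0.09) vs (0.69, 0.17, 0.15) for the confounded
expression fixture, delays {WCGW 0.15, SCGW 0.05, SCGS 0} at coverage 50,
base methylation 0.8, G1:S:G2M = 5:3:2 pseudo-mix. Where no value is
prescribed anywhere, one realistic value was fixed once: NB dispersion 0.4,
dropout midpoint 1 and slope 1.5 on log(mean+1), 500 bp synthetic peaks,
mitochondrial fractions ~ Beta(2, 38).

What passing tests show is that the corrections remove exactly the
artifacts this generator plants — rank-threshold dosage, binomial
methylation delay, multiplicative phase effects. Real data add mappability
and GC sequence effects, per-cell cycle-position continuity, batch
structure, and non-CpG context effects that the generator deliberately
omits; results on real data depend on those layers being handled upstream.

# Fixture sizes and numerical choices

* The depth fixtures use 5000 windows of 5 kb at 100 reads/window averaged
  over 5–10 seeds. The 5 kb window size pairs with the strict > 5 kb
  length filter so an isolated noisy window cannot become a call — the role
  the external callers' internal smoothing plays at larger windows. At 100
  reads/window the Poisson log2 noise floor (≈ 0.15 s.d.) sits close to the
  0.25 cutoff, which is what makes the uncorrected pseudo-CNV load visible.
* Spike-recovery fixtures use 5000 reads/window (high coverage) with
  120 kb spikes at multipliers 1.5/0.5, where recovery is limited by the
  correction, not by shot noise.
* The stratum-width refinement property is demonstrated at 2000
  reads/window: below that, the post-correction residual correlation is at
  the sampling-noise floor (≈ 0.01) for every width and ordering between
  widths is noise.
* DMR calibration uses 20 × 2000 null tiles (Binomial(30, 0.5) both sides)
  and expects ≤ 1 false call in total at the joint thresholds; power uses
  6-CpG tiles at 30× with a planted 40-point difference.
* All randomness flows from one integer master seed through
  `derive_seed(seed, key)`, a splittable multiplicative hash, so unrelated
  operations never share an RNG stream and every pipeline output is
  bit-reproducible given the seed.

# Known limitations

* The hurdle test is a calibrated stand-in for external hurdle-model tools,
  not a reimplementation; equivalence is not claimed (null uniformity and
  power on planted effects are).
* Per-cell CPM normalisation (see above); no TMM-style composition
  correction.
* `onset_spr` is a labelled heuristic: the escalation point of a sweep is
  an empirical observation, not a defined statistic.
* No mappability or sequence-level GC modelling; GC is a per-window
  covariate.
* Sex-chromosome ploidy, multi-sample joint calling, and breakpoint
  refinement are out of scope.

# A worked pass through the pipeline

```{r, eval = FALSE}
library(cyclegate)

g  <- make_genome(5000, bin_size = 5000, rt_amplitude = 2, seed = 1)
tr <- simulate_wgs_bins(g, phase_composition(0.30, 0.55, 0.15),
                        n_cells = 200, mean_depth = 100, seed = 1)

track_rt_correlation(depth_log2ratio(tr, 1), g$rt)      # ~0.7 uncorrected
corrected <- correct_by_covariate(tr, g$rt, "rt")$track
track_rt_correlation(depth_log2ratio(corrected, 1), g$rt)  # ~0

before <- assign_rt(segment_track(depth_log2ratio(tr, 1), g), g)
after  <- segment_track(depth_log2ratio(corrected, 1), g)
enrichment_scores(before)          # gains pile into early RT before correction
nrow(after) / nrow(before)         # pseudo-CNV suppression
```
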
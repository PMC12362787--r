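# Open-chromatin set logic under cell-cycle phasing: pseudo-mix sampling
# fractions, peak merging and canonical/phase-specific set construction,
# RT labelling of peaks with the +/-0.25 rule, openness-by-expression
# regulatory groups, and OCR-CNV overlap with random placement controls.

#' Sampling fractions for a pseudo-mix at a target phase ratio
#'
#' Given per-phase read totals, returns the per-phase retention fractions
#' that realise the target G1:S:G2M ratio exactly in expectation. The
#' binding reference phase (the one whose reads are scarcest relative to
#' its target share) is retained at fraction 1.
#'
#' @param read_totals Named numeric vector of per-phase read totals
#'   (names `G1`, `S`, `G2M`).
#' @param target_ratio Target mixing ratio, same names (default 5:3:2).
#' @return Named fractions in `(0, 1]`, reference phase exactly 1.
#' @export
pseudo_mix_fractions <- function(read_totals, target_ratio = c(G1 = 5, S = 3, G2M = 2)) {
  phases <- names(target_ratio)
  if (!all(phases %in% names(read_totals))) stopf("read totals must name every phase")
  totals <- read_totals[phases]
  if (any(totals <= 0)) stopf("all phase read totals must be positive")
  if (any(target_ratio <= 0)) stopf("target ratio entries must be positive")
  ref <- phases[which.max(target_ratio / totals)]
  required <- target_ratio / target_ratio[[ref]] * totals[[ref]]
  fractions <- required / totals
  fractions[[ref]] <- 1
  fractions
}

#' Merge peak sets by >= 1 bp overlap
#'
#' Intervals overlapping by at least one base are combined; book-ended
#' intervals (zero overlap) are left separate.
#'
#' @param sets A [peak_set()] or list of them (or plain interval
#'   data.frames).
#' @return A merged, sorted, non-overlapping [peak_set()].
#' @export
merge_peaks <- function(sets) {
  if (is.data.frame(sets)) sets <- list(sets)
  df <- do.call(rbind, lapply(sets, function(s) as.data.frame(s)[c("chrom", "start", "end")]))
  if (nrow(df) == 0) return(peak_set(df))
  gr <- GenomicRanges::reduce(gr_from_intervals(df), min.gapwidth = 0L)
  peak_set(intervals_from_gr(gr))
}

#' Canonical, phase-specific and pseudo-mix-specific OCR sets
#'
#' Canonical OCRs are the base-pair intersection cores present in all three
#' phases. A phase's specific OCRs are its peaks with no >= 1 bp overlap in
#' the pseudo-mix; pseudo-mix-specific OCRs are pseudo-mix peaks with no
#' overlap in the canonical set.
#'
#' @param per_phase Named list of [peak_set()]s for `G1`, `S`, `G2M`.
#' @param pseudo_mix The pseudo-mix [peak_set()].
#' @return List with `canonical`, `phase_specific` (named list) and
#'   `pseudo_mix_specific`.
#' @export
ocr_set_logic <- function(per_phase, pseudo_mix) {
  if (!all(c("G1", "S", "G2M") %in% names(per_phase))) stopf("need G1, S and G2M peak sets")
  grs <- lapply(per_phase, function(s) GenomicRanges::reduce(gr_from_intervals(s), min.gapwidth = 0L))
  pm <- GenomicRanges::reduce(gr_from_intervals(pseudo_mix), min.gapwidth = 0L)
  canonical <- Reduce(function(a, b) GenomicRanges::intersect(a, b), grs)
  spec <- lapply(per_phase, function(s) {
    gr <- gr_from_intervals(s)
    hits <- GenomicRanges::countOverlaps(gr, pm, minoverlap = 1L)
    peak_set(as.data.frame(s)[hits == 0, c("chrom", "start", "end"), drop = FALSE])
  })
  pm_gr <- gr_from_intervals(pseudo_mix)
  pm_hits <- GenomicRanges::countOverlaps(pm_gr, canonical, minoverlap = 1L)
  list(
    canonical = peak_set(intervals_from_gr(canonical)),
    phase_specific = spec,
    pseudo_mix_specific = peak_set(
      as.data.frame(pseudo_mix)[pm_hits == 0, c("chrom", "start", "end"), drop = FALSE])
  )
}

#' Label peaks by replication timing with the +/-0.25 rule
#'
#' Each peak's RT score is the maximum RT over overlapping genome bins
#' (the same max rule used for CNV segments); scores above `+cutoff` are
#' `"earlier"`, below `-cutoff` `"later"`, and everything else (including
#' exactly `+/-cutoff`, warned) `"no_change"`.
#'
#' @param peaks A [peak_set()] or interval data.frame.
#' @param genome A `genome_model`.
#' @param rt Per-bin RT vector (defaults to `genome$rt`).
#' @param cutoff Labelling threshold (default 0.25).
#' @return The peaks with `rt_score` and `rt_label` columns added.
#' @export
assign_ocr_rt <- function(peaks, genome, rt = genome$rt, cutoff = 0.25) {
  stopifnot(inherits(genome, "genome_model"))
  df <- as.data.frame(peaks)
  df$rt_score <- NA_real_
  for (i in seq_len(nrow(df))) {
    hit <- genome$bins$chrom == df$chrom[i] &
      genome$bins$start < df$end[i] & genome$bins$end > df$start[i]
    if (!any(hit)) stopf("peak %s:%d-%d overlaps no bin", df$chrom[i], df$start[i], df$end[i])
    df$rt_score[i] <- max(rt[hit])
  }
  if (any(abs(df$rt_score) == cutoff)) {
    warnf("peak(s) with rt_score exactly +/-%g labelled no_change", cutoff)
  }
  df$rt_label <- ifelse(df$rt_score > cutoff, "earlier",
                        ifelse(df$rt_score < -cutoff, "later", "no_change"))
  df
}

#' Five openness-by-expression regulatory groups
#'
#' `More_Open` genes exceed the `hi_quantile` of the openness statistic;
#' `Less_Open` genes fall below `lo_openness`. `Hi_Exp` genes exceed the
#' `hi_quantile` of TPM; `Lo_Exp` genes fall below `lo_tpm`. The group is
#' the cross of the two axes when both are determined, else `None`.
#'
#' @param openness_stat Per-gene openness statistic (e.g. maximum
#'   accessibility TPM over peaks overlapping the gene).
#' @param tpm Per-gene expression TPM.
#' @param hi_quantile Upper quantile for the "more"/"high" side (0.75).
#' @param lo_openness,lo_tpm Lower cutoffs for the "less"/"low" side (1.0).
#' @return data.frame with `openness_stat`, `expression_tpm`, `group`.
#' @export
gene_openness_expression_groups <- function(openness_stat, tpm,
                                            hi_quantile = 0.75,
                                            lo_openness = 1.0, lo_tpm = 1.0) {
  if (length(openness_stat) != length(tpm)) stopf("length mismatch")
  if (length(tpm) < 4) stopf("need at least 4 genes for quantile thresholds")
  if (any(!is.finite(openness_stat)) || any(!is.finite(tpm))) stopf("non-finite input")
  open_hi <- openness_stat > stats::quantile(openness_stat, hi_quantile)
  open_lo <- !open_hi & openness_stat < lo_openness
  exp_hi <- tpm > stats::quantile(tpm, hi_quantile)
  exp_lo <- !exp_hi & tpm < lo_tpm
  open_axis <- ifelse(open_hi, "More_Open", ifelse(open_lo, "Less_Open", NA))
  exp_axis <- ifelse(exp_hi, "Hi_Exp", ifelse(exp_lo, "Lo_Exp", NA))
  group <- ifelse(!is.na(open_axis) & !is.na(exp_axis),
                  paste(open_axis, exp_axis, sep = "-"), "None")
  data.frame(openness_stat = openness_stat, expression_tpm = tpm, group = group,
             stringsAsFactors = FALSE)
}

#' Transcripts-per-million from feature counts
#'
#' Counting windows are extended `upstream_extension` bp upstream, so the
#' effective length is `length + upstream_extension`; rates are normalised
#' to sum to one million.
#'
#' @param counts Per-feature read counts.
#' @param lengths Per-feature lengths in bp (positive).
#' @param upstream_extension Upstream extension used at counting (2000 bp).
#' @return Per-feature TPM summing to 1e6.
#' @export
tpm_from_counts <- function(counts, lengths, upstream_extension = 2000L) {
  if (length(counts) != length(lengths)) stopf("length mismatch")
  if (any(lengths <= 0)) stopf("feature lengths must be positive")
  if (all(counts == 0)) stopf("all-zero counts")
  rate <- counts / (lengths + upstream_extension)
  rate / sum(rate) * 1e6
}

#' OCR-CNV overlap ratios with random placement controls
#'
#' For each named CNV set, the observed ratio is the fraction of CNV bases
#' covered by the OCRs. The control re-places length-matched intervals
#' uniformly at random within chromosomes (chromosome chosen proportional
#' to its length) `n_random` times and reports the mean and SD of the
#' control ratio.
#'
#' @param ocrs A [peak_set()] or interval data.frame.
#' @param cnv_sets Named list of interval data.frames.
#' @param genome A `genome_model` defining chromosome extents.
#' @param n_random Number of random placements (default 1000).
#' @param seed Integer seed.
#' @return data.frame with one row per CNV set: `set`, `observed_ratio`,
#'   `random_mean`, `random_sd`, `n_random`.
#' @export
ocr_cnv_overlap <- function(ocrs, cnv_sets, genome, n_random = 1000L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_random < 1) stopf("`n_random` must be >= 1")
  ocr_df <- as.data.frame(ocrs)[, c("chrom", "start", "end"), drop = FALSE]
  chroms <- unique(genome$bins$chrom)
  ext <- do.call(rbind, lapply(chroms, function(ch) {
    b <- genome$bins[genome$bins$chrom == ch, ]
    data.frame(chrom = ch, lo = min(b$start), hi = max(b$end))
  }))
  len_chrom <- ext$hi - ext$lo
  out <- lapply(names(cnv_sets), function(nm) {
    cnv <- cnv_sets[[nm]]
    if (nrow(cnv) == 0) {
      return(data.frame(set = nm, observed_ratio = NA_real_, random_mean = NA_real_,
                        random_sd = NA_real_, n_random = n_random))
    }
    lens <- cnv$end - cnv$start
    if (any(lens > max(len_chrom))) stopf("CNV interval longer than every chromosome")
    obs <- if (nrow(ocr_df) == 0) 0 else region_overlap_ratio(cnv, ocr_df)
    rnd <- with_op_seed(seed, paste0("cnv-overlap-", nm), {
      vapply(seq_len(n_random), function(r) {
        ok <- len_chrom >= max(lens)
        ci <- sample(which(ok), length(lens), replace = TRUE, prob = len_chrom[ok])
        start <- ext$lo[ci] + floor(stats::runif(length(lens)) * (len_chrom[ci] - lens + 1))
        rand <- data.frame(chrom = ext$chrom[ci], start = start, end = start + lens)
        if (nrow(ocr_df) == 0) 0 else region_overlap_ratio(rand, ocr_df)
      }, 0)
    })
    data.frame(set = nm, observed_ratio = obs, random_mean = mean(rnd),
               random_sd = stats::sd(rnd), n_random = n_random)
  })
  do.call(rbind, out)
}
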
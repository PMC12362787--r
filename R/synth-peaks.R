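# Synthetic per-phase peak sets: a shared backbone identical across phases
# plus phase-specific peaks; S-specific peaks can be biased toward
# early-replicating bins.

#' Construct a peak set
#'
#' @param intervals data.frame with `chrom`, `start`, `end` (0-based
#'   half-open), sorted.
#' @param phase_tag One of `G1`, `S`, `G2M`, `pseudo_mix`.
#' @return An object of class `peak_set` (a data.frame with a phase tag).
#' @export
peak_set <- function(intervals, phase_tag = NA_character_) {
  stopifnot(is.data.frame(intervals))
  if (nrow(intervals) > 0) {
    if (any(intervals$end <= intervals$start)) stopf("peaks must have end > start")
    intervals <- intervals[order(intervals$chrom, intervals$start), , drop = FALSE]
    rownames(intervals) <- NULL
  }
  structure(intervals, class = c("peak_set", "data.frame"), phase_tag = phase_tag)
}

#' Simulate a phase's peak set on a genome
#'
#' Shared peaks are placed uniformly over bins using a seed stream that does
#' not depend on `phase`, so all phases receive the identical backbone.
#' Phase-specific peaks for the S phase are placed with probability
#' proportional to `exp(s_early_bias * rt)`; other phases place their
#' specific peaks uniformly.
#'
#' @param genome A `genome_model`.
#' @param phase Phase label (`G1`, `S`, `G2M`).
#' @param n_shared Number of shared backbone peaks.
#' @param n_specific Number of phase-specific peaks.
#' @param s_early_bias Non-negative exponential tilt of S-specific peaks
#'   toward early RT.
#' @param peak_width Width of each synthetic peak in bp.
#' @param seed Integer seed.
#' @return A [peak_set()].
#' @export
simulate_peaks <- function(genome, phase, n_shared, n_specific,
                           s_early_bias = 0, peak_width = 500L, seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  if (n_shared < 0 || n_specific < 0) stopf("peak counts must be >= 0")
  if (s_early_bias < 0) stopf("`s_early_bias` must be >= 0")
  nb <- n_bins(genome)
  if (n_shared + n_specific > nb) stopf("more peaks than bins")

  shared_bins <- with_op_seed(seed, "peaks-shared", sample.int(nb, n_shared))
  spec_bins <- with_op_seed(seed, paste0("peaks-", phase), {
    pool <- setdiff(seq_len(nb), shared_bins)
    if (n_specific == 0) integer(0)
    else if (identical(phase, "S") && s_early_bias > 0) {
      w <- exp(s_early_bias * genome$rt[pool])
      pool[sample.int(length(pool), n_specific, prob = w)]
    } else {
      pool[sample.int(length(pool), n_specific)]
    }
  })
  idx <- sort(c(shared_bins, spec_bins))
  b <- genome$bins[idx, , drop = FALSE]
  centre <- (b$start + b$end) %/% 2L
  half <- peak_width %/% 2L
  peak_set(
    data.frame(chrom = b$chrom,
               start = pmax(b$start, centre - half),
               end = pmin(b$end, centre - half + peak_width),
               stringsAsFactors = FALSE),
    phase_tag = phase
  )
}
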
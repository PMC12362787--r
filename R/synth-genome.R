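# Synthetic genome model: the binned substrate every depth-based analysis
# works on. Replication timing (RT) is a smooth signed score per bin
# (positive = early-replicating), GC a per-bin fraction.

#' Construct a genome model
#'
#' @param bins data.frame with columns `chrom`, `start`, `end` (0-based
#'   half-open, sorted, non-overlapping).
#' @param bin_size Nominal bin width in bp.
#' @param gc Per-bin GC fraction in `[0, 1]`.
#' @param rt Per-bin signed replication-timing score (positive = early).
#' @param seed Integer seed the model was generated from (bookkeeping).
#' @return An object of class `genome_model`.
#' @export
genome_model <- function(bins, bin_size, gc, rt, seed = NA_integer_) {
  stopifnot(is.data.frame(bins), all(c("chrom", "start", "end") %in% names(bins)))
  n <- nrow(bins)
  if (length(gc) != n || length(rt) != n) stopf("gc/rt length must equal bin count")
  check_fraction(gc, "gc")
  if (any(bins$end <= bins$start)) stopf("bins must have positive width")
  for (ch in unique(bins$chrom)) {
    b <- bins[bins$chrom == ch, ]
    if (is.unsorted(b$start, strictly = TRUE)) stopf("bins must be sorted within chromosome")
    if (any(b$start[-1] < b$end[-nrow(b)])) stopf("bins must be non-overlapping")
  }
  structure(
    list(bins = bins, bin_size = as.integer(bin_size), gc = as.numeric(gc),
         rt = as.numeric(rt), seed = seed),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat(sprintf("genome_model: %d bins of %d bp on %d chromosome(s); RT range [%.3g, %.3g]\n",
              n_bins(x), x$bin_size, length(unique(x$bins$chrom)),
              min(x$rt), max(x$rt)))
  invisible(x)
}

#' Number of bins in a genome model
#' @param genome A `genome_model`.
#' @return Integer bin count.
#' @export
n_bins <- function(genome) nrow(genome$bins)

#' Generate a synthetic genome with smooth replication timing
#'
#' RT is a low-frequency sum of sinusoids (domain-like smooth structure),
#' centred and scaled to `[-rt_amplitude, rt_amplitude]`. GC is constructed
#' with a controlled Pearson correlation to RT: an orthogonalised noise
#' component is mixed with the standardised RT signal so the realised
#' correlation matches `gc_rt_corr` closely at large bin counts.
#'
#' @param n_bins Total number of bins (split near-evenly over chromosomes).
#' @param bin_size Bin width in bp.
#' @param n_chroms Number of chromosomes.
#' @param rt_amplitude Half-range of the RT score.
#' @param gc_rt_corr Target Pearson correlation between GC and RT, in `[-1, 1]`.
#' @param seed Integer seed; output is deterministic given the seed.
#' @return A `genome_model`.
#' @export
make_genome <- function(n_bins, bin_size = 10000L, n_chroms = 1L,
                        rt_amplitude = 2, gc_rt_corr = 0, seed = 1L) {
  if (n_bins < 1 || bin_size < 1) stopf("`n_bins` and `bin_size` must be positive")
  if (n_chroms < 1 || n_bins < n_chroms) stopf("need n_bins >= n_chroms >= 1")
  if (abs(gc_rt_corr) > 1) stopf("`gc_rt_corr` must lie in [-1, 1]")
  with_op_seed(seed, "genome", {
    per <- rep(n_bins %/% n_chroms, n_chroms)
    extra <- n_bins %% n_chroms
    if (extra > 0) per[seq_len(extra)] <- per[seq_len(extra)] + 1L
    chrom <- rep(paste0("chr", seq_len(n_chroms)), per)
    start <- unlist(lapply(per, function(k) (seq_len(k) - 1L) * bin_size),
                    use.names = FALSE)
    bins <- data.frame(chrom = chrom, start = start, end = start + bin_size)

    # smooth RT per chromosome: 4 sinusoids with periods 40-400 bins
    rt <- numeric(n_bins)
    off <- 0L
    for (k in per) {
      t <- seq_len(k)
      sig <- numeric(k)
      for (j in 1:4) {
        period <- stats::runif(1, 40, 400)
        sig <- sig + stats::runif(1, 0.4, 1) * sin(2 * pi * t / period + stats::runif(1, 0, 2 * pi))
      }
      rt[off + t] <- sig
      off <- off + k
    }
    rt <- rt - mean(rt)
    rt <- rt / max(abs(rt)) * rt_amplitude

    z_rt <- as.numeric(scale(rt))
    noise <- stats::rnorm(n_bins)
    if (n_bins > 2) {
      noise <- stats::residuals(stats::lm(noise ~ z_rt))  # exact orthogonality
      noise <- as.numeric(scale(noise))
    }
    z_gc <- gc_rt_corr * z_rt + sqrt(max(0, 1 - gc_rt_corr^2)) * noise
    gc <- pmin(1, pmax(0, 0.45 + 0.08 * z_gc))
    genome_model(bins, bin_size, gc, rt, seed = as.integer(seed))
  })
}

#' Describe a cell-cycle phase composition
#'
#' @param g1,s,g2m Non-negative phase fractions summing to 1.
#' @return An object of class `phase_composition`.
#' @export
phase_composition <- function(g1, s, g2m) {
  v <- c(g1 = g1, s = s, g2m = g2m)
  if (any(v < 0)) stopf("phase fractions must be non-negative")
  if (abs(sum(v) - 1) > 1e-9) stopf("phase fractions must sum to 1")
  structure(as.list(v), class = "phase_composition")
}

#' Define a ground-truth copy-number spike
#'
#' @param chrom,start,end Interval (0-based half-open) receiving the spike.
#' @param copy_multiplier Positive multiplier on per-cell copy number
#'   (1.5 = heterozygous gain, 0.5 = heterozygous loss).
#' @return An object of class `cnv_spike`.
#' @export
cnv_spike <- function(chrom, start, end, copy_multiplier) {
  if (end <= start) stopf("spike must have end > start")
  if (copy_multiplier <= 0) stopf("copy multiplier must be positive")
  structure(list(chrom = chrom, start = start, end = end,
                 copy_multiplier = copy_multiplier),
            class = "cnv_spike")
}

#' Simulate pooled binned read depth under a phase composition
#'
#' Each G1 cell contributes copy 1 per bin and each G2M cell copy 2. Each
#' S-phase cell draws a replication progression `u ~ U(0,1)` and has copy 2
#' in the earliest-replicating fraction `u` of bins (by descending RT
#' percentile rank), copy 1 elsewhere — so pooled depth couples monotonically
#' to RT in proportion to the S-phase ratio. Spikes multiply copy number.
#' Bin counts are Poisson with mean proportional to `mean_depth` times the
#' summed copy state.
#'
#' @param genome A `genome_model`.
#' @param composition A `phase_composition`.
#' @param n_cells Number of cells in the pool.
#' @param mean_depth Expected reads per bin for the pool.
#' @param spikes List of [cnv_spike()] objects (may be empty).
#' @param seed Integer seed.
#' @return A [bin_track()] of simulated counts.
#' @export
simulate_wgs_bins <- function(genome, composition, n_cells = 200L,
                              mean_depth = 100, spikes = list(), seed = 1L) {
  stopifnot(inherits(genome, "genome_model"), inherits(composition, "phase_composition"))
  if (n_cells < 1) stopf("`n_cells` must be >= 1")
  if (mean_depth <= 0) stopf("`mean_depth` must be positive")
  nb <- n_bins(genome)

  mult <- rep(1, nb)
  for (sp in spikes) {
    stopifnot(inherits(sp, "cnv_spike"))
    hit <- genome$bins$chrom == sp$chrom &
      genome$bins$start < sp$end & genome$bins$end > sp$start
    if (!any(hit)) stopf("spike %s:%d-%d overlaps no genome bin", sp$chrom, sp$start, sp$end)
    if (sp$start < min(genome$bins$start[genome$bins$chrom == sp$chrom]) ||
        sp$end > max(genome$bins$end[genome$bins$chrom == sp$chrom])) {
      stopf("spike %s:%d-%d extends outside the genome", sp$chrom, sp$start, sp$end)
    }
    mult[hit] <- mult[hit] * sp$copy_multiplier
  }

  with_op_seed(seed, "wgs", {
    n_phase <- as.vector(stats::rmultinom(1, n_cells, prob = c(composition$g1, composition$s, composition$g2m)))
    n_g1 <- n_phase[1]; n_s <- n_phase[2]; n_g2m <- n_phase[3]
    # descending RT percentile rank: earliest bin has the smallest rank fraction
    rank_frac <- (rank(-genome$rt, ties.method = "first") - 0.5) / nb
    n_replicated <- if (n_s > 0) {
      u <- sort(stats::runif(n_s))
      n_s - findInterval(rank_frac, u)  # S cells with u >= rank_frac
    } else rep(0L, nb)
    copy <- (n_g1 + n_s + 2 * n_g2m + n_replicated) * mult
    lambda <- mean_depth * copy / mean(copy)
    counts <- stats::rpois(nb, lambda)
    bin_track(genome, counts)
  })
}
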
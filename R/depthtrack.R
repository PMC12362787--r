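# Binned read-depth tracks and their covariate corrections. The central
# operation rescales each window's depth by m / m_stratum, where m is the
# reference median over all windows and m_stratum the median over windows
# sharing the window's (discretised) normalised covariate value. Applied
# with replication timing as the covariate this removes the depth excess
# that asynchronously replicating S-phase cells place on early domains.

#' Construct a bin track
#'
#' @param genome A `genome_model` the counts are indexed against.
#' @param count Non-negative per-bin read depth.
#' @param m Reference median. Defaults to `median(count)`; corrections that
#'   preserve the per-stratum median set it explicitly (the correction maps
#'   every stratum's median onto `m`, so `m` remains a median of the
#'   corrected counts).
#' @return An object of class `bin_track`.
#' @export
bin_track <- function(genome, count, m = stats::median(count)) {
  stopifnot(inherits(genome, "genome_model"))
  if (length(count) != n_bins(genome)) stopf("count length must equal bin count")
  if (any(!is.finite(count))) stopf("non-finite counts")
  if (any(count < 0)) stopf("counts must be non-negative")
  structure(list(genome = genome, count = as.numeric(count), m = m),
            class = "bin_track")
}

#' @export
print.bin_track <- function(x, ...) {
  cat(sprintf("bin_track: %d bins, median %.4g, total %.4g reads\n",
              length(x$count), x$m, sum(x$count)))
  invisible(x)
}

#' Count read starts per genome bin
#'
#' A read whose start lies in `[bin.start, bin.end)` is assigned to that bin
#' (0-based half-open convention).
#'
#' @param read_starts data.frame with columns `chrom` and `pos` (0-based).
#' @param genome A `genome_model`.
#' @param drop_unplaced Silently drop reads on unknown chromosomes or outside
#'   the binned extent instead of erroring.
#' @return A [bin_track()].
#' @export
bin_reads <- function(read_starts, genome, drop_unplaced = FALSE) {
  stopifnot(inherits(genome, "genome_model"))
  counts <- numeric(n_bins(genome))
  if (nrow(read_starts) > 0) {
    known <- unique(genome$bins$chrom)
    bad <- !(read_starts$chrom %in% known)
    if (any(bad)) {
      if (!drop_unplaced) stopf("reads on unknown chromosome(s): %s",
                                paste(unique(read_starts$chrom[bad]), collapse = ", "))
      read_starts <- read_starts[!bad, , drop = FALSE]
    }
    for (ch in unique(read_starts$chrom)) {
      bsel <- which(genome$bins$chrom == ch)
      starts <- genome$bins$start[bsel]
      ends <- genome$bins$end[bsel]
      pos <- read_starts$pos[read_starts$chrom == ch]
      idx <- findInterval(pos, starts)
      inside <- idx >= 1 & pos < ends[pmax(idx, 1)]
      if (any(!inside) && !drop_unplaced) stopf("read position outside binned extent on %s", ch)
      tab <- tabulate(idx[inside], nbins = length(bsel))
      counts[bsel] <- counts[bsel] + tab
    }
  }
  bin_track(genome, counts)
}

#' Per-bin log2 depth ratio against the track median
#'
#' `log2((count + pseudocount) / (m + pseudocount))`.
#'
#' @param track A [bin_track()].
#' @param pseudocount Non-negative stabiliser; required when `m = 0`.
#' @return Numeric vector, one value per bin.
#' @export
depth_log2ratio <- function(track, pseudocount = 0) {
  stopifnot(inherits(track, "bin_track"))
  if (track$m <= 0 && pseudocount <= 0) stopf("degenerate track: median is 0 and pseudocount is 0")
  log2((track$count + pseudocount) / (track$m + pseudocount))
}

#' Correct a depth track by a per-bin covariate (GC or replication timing)
#'
#' Windows are stratified by the floor-discretised normalised covariate
#' (`kind = "rt"` first divides by the maximum absolute covariate value so
#' late domains keep their sign inside `[-1, 1]`; `kind = "gc"` uses the GC
#' fraction as is) and every window is rescaled by `m / m_stratum`, where
#' `m_stratum` is the median depth of its stratum. Strata whose median is
#' zero pass counts through unchanged with a warning. The corrected track
#' keeps `m` as its reference median: the rescaling maps each stratum's
#' median exactly onto `m`, so `m` remains a median of the corrected counts
#' and the correction is idempotent.
#'
#' @param track A [bin_track()].
#' @param covariate Per-bin numeric covariate (finite).
#' @param kind `"gc"` or `"rt"`.
#' @param bin_width Stratum width on the normalised covariate scale.
#' @return List with elements `track` (corrected [bin_track()]) and `model`
#'   (a `correction_model` with the per-stratum medians).
#' @export
correct_by_covariate <- function(track, covariate, kind = c("rt", "gc"),
                                 bin_width = 0.01) {
  stopifnot(inherits(track, "bin_track"))
  kind <- match.arg(kind)
  if (length(covariate) != length(track$count)) stopf("covariate length mismatch")
  if (any(!is.finite(covariate))) stopf("non-finite covariate")
  if (bin_width <= 0) stopf("`bin_width` must be positive")
  if (all(track$count == 0)) stopf("all-zero track")

  max_norm <- if (kind == "rt") max(abs(covariate)) else 1
  if (max_norm == 0) max_norm <- 1
  norm <- covariate / max_norm
  stratum <- floor(norm / bin_width)
  m <- track$m
  med <- tapply(track$count, stratum, stats::median)
  m_str <- med[as.character(stratum)]
  factor <- ifelse(m_str > 0, m / m_str, 1)
  if (any(m_str == 0)) warnf("%d stratum(s) with zero median depth passed through uncorrected",
                             sum(med == 0))
  corrected <- track$count * factor
  model <- structure(list(covariate = kind, bin_width = bin_width,
                          stratum_median = med, max_norm = max_norm, m = m),
                     class = "correction_model")
  list(track = bin_track(track$genome, corrected, m = m), model = model)
}

#' Residual-based (LASSO) covariate correction
#'
#' Fits an L1-penalised linear model of depth on degree-3 polynomial
#' covariate features and returns `residual + m` (clipped at zero with a
#' warning). With `l1_penalty = 0` this is an ordinary least-squares fit.
#'
#' @param track A [bin_track()].
#' @param covariate Per-bin numeric covariate.
#' @param l1_penalty Non-negative LASSO penalty (glmnet `lambda`).
#' @return A corrected [bin_track()].
#' @export
residual_correct <- function(track, covariate, l1_penalty = 0) {
  stopifnot(inherits(track, "bin_track"))
  if (length(covariate) != length(track$count)) stopf("covariate length mismatch")
  if (any(!is.finite(covariate))) stopf("non-finite covariate")
  if (l1_penalty < 0) stopf("`l1_penalty` must be >= 0")
  y <- track$count
  if (l1_penalty == 0) {
    if (stats::sd(covariate) == 0) stopf("singular design: constant covariate with zero penalty")
    fit <- stats::lm(y ~ stats::poly(covariate, 3))
    resid <- stats::residuals(fit)
  } else {
    x <- stats::poly(covariate, 3, raw = FALSE)
    fit <- glmnet::glmnet(x, y, alpha = 1, lambda = l1_penalty,
                          standardize = TRUE, intercept = TRUE)
    resid <- y - as.numeric(stats::predict(fit, newx = x))
  }
  corrected <- resid + track$m
  if (any(corrected < 0)) {
    warnf("%d corrected value(s) clipped at 0", sum(corrected < 0))
    corrected <- pmax(corrected, 0)
  }
  bin_track(track$genome, corrected)
}

#' Pearson correlation between a log2 depth profile and replication timing
#'
#' The p-value comes from the two-sided t statistic
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)`.
#'
#' @param log2ratio Per-bin log2 depth ratio.
#' @param rt Per-bin replication-timing score.
#' @return List with `r`, `n` and `p` (class `correlation_result`).
#' @export
track_rt_correlation <- function(log2ratio, rt) {
  if (length(log2ratio) != length(rt)) stopf("length mismatch")
  if (length(log2ratio) < 3) stopf("need at least 3 bins")
  if (any(!is.finite(log2ratio)) || any(!is.finite(rt))) stopf("non-finite values")
  if (stats::sd(log2ratio) == 0 || stats::sd(rt) == 0) {
    stopf("undefined correlation: zero variance")
  }
  ct <- stats::cor.test(log2ratio, rt, method = "pearson")
  structure(list(r = unname(ct$estimate), n = length(rt), p = ct$p.value),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (n = %d, p = %.3g)\n", x$r, x$n, x$p))
  invisible(x)
}
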
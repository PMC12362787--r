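# Two-population read-mixing algebra: sample fraction x of a high-SPR
# library and fraction y of a low-SPR library so that the mixture keeps the
# high-SPR library's total read count while achieving a prescribed S-phase
# ratio. Solving
#   x * RC_esc + y * RC_mef               = RC_esc
#   x * S_esc * RC_esc + y * S_mef * RC_mef = S_ratio * RC_esc
# gives x = (S_ratio - S_mef) / (S_esc - S_mef) and
# y = (1 - x) * RC_esc / RC_mef.

#' Specify a two-population mixture
#'
#' @param s_esc,s_mef S-phase ratios of the high- and low-SPR populations
#'   (`0 <= s_mef < s_esc <= 1`).
#' @param rc_esc,rc_mef Total read counts of the two libraries.
#' @param s_ratio Target S-phase ratio of the mixture, inside
#'   `[s_mef, s_esc]`.
#' @return An object of class `mixture_spec`.
#' @export
mixture_spec <- function(s_esc, s_mef, rc_esc, rc_mef, s_ratio) {
  check_fraction(c(s_esc, s_mef, s_ratio), "S fractions")
  if (s_esc == s_mef) stopf("degenerate system: s_esc == s_mef")
  if (s_mef > s_esc) stopf("need s_mef < s_esc")
  if (rc_esc <= 0 || rc_mef <= 0) stopf("read counts must be positive")
  if (s_ratio < s_mef || s_ratio > s_esc) stopf("infeasible mixture: s_ratio outside [s_mef, s_esc]")
  structure(list(s_esc = s_esc, s_mef = s_mef, rc_esc = rc_esc,
                 rc_mef = rc_mef, s_ratio = s_ratio),
            class = "mixture_spec")
}

#' Solve for the sampling fractions achieving a target S-phase ratio
#'
#' Closed form: `x = (s_ratio - s_mef) / (s_esc - s_mef)` and
#' `y = (1 - x) * rc_esc / rc_mef`. The pair preserves the high-SPR
#' library's total read count exactly and hits the target SPR.
#'
#' @param spec A [mixture_spec()].
#' @return List with fractions `x` and `y` (class `mixture_solution`).
#' @export
solve_mixture_fractions <- function(spec) {
  stopifnot(inherits(spec, "mixture_spec"))
  x <- (spec$s_ratio - spec$s_mef) / (spec$s_esc - spec$s_mef)
  y <- (1 - x) * spec$rc_esc / spec$rc_mef
  structure(list(x = x, y = y), class = "mixture_solution")
}

#' @export
print.mixture_solution <- function(x, ...) {
  cat(sprintf("mixture_solution: x = %.7f, y = %.8f\n", x$x, x$y))
  invisible(x)
}

#' Mix two bin tracks by binomial thinning
#'
#' Each bin receives `Binomial(count_a, x) + Binomial(count_b, y)` reads,
#' which matches the distribution of random read-level subsampling for any
#' bin-count statistic.
#'
#' @param track_a,track_b [bin_track()]s on the same genome.
#' @param x,y Retention fractions in `[0, 1]`.
#' @param seed Integer seed.
#' @return A mixed [bin_track()].
#' @export
mix_bin_counts <- function(track_a, track_b, x, y, seed = 1L) {
  stopifnot(inherits(track_a, "bin_track"), inherits(track_b, "bin_track"))
  if (!identical(track_a$genome$bins, track_b$genome$bins)) stopf("tracks must share a genome")
  check_fraction(c(x, y), "retention fractions")
  with_op_seed(seed, "mix", {
    counts <- stats::rbinom(length(track_a$count), round(track_a$count), x) +
      stats::rbinom(length(track_b$count), round(track_b$count), y)
    bin_track(track_a$genome, counts)
  })
}

#' Downsample a bin track to a fraction of its reads
#'
#' Per-bin binomial thinning, the bin-count equivalent of random read
#' subsampling to a lower sequencing depth.
#'
#' @param track A [bin_track()].
#' @param fraction Retention fraction in `(0, 1]`.
#' @param seed Integer seed.
#' @return A thinned [bin_track()].
#' @export
downsample_counts <- function(track, fraction, seed = 1L) {
  stopifnot(inherits(track, "bin_track"))
  if (fraction <= 0 || fraction > 1) stopf("`fraction` must lie in (0, 1]")
  if (fraction == 1) return(track)
  with_op_seed(seed, "downsample", {
    bin_track(track$genome, stats::rbinom(length(track$count), round(track$count), fraction))
  })
}

#' Sweep the S-phase ratio and measure pseudo-CNV emergence
#'
#' For every (SPR, depth, replicate) cell, two endpoint pools are simulated
#' on `genome` (a high-SPR and a low-SPR composition), mixed with the
#' fractions solving the mixture algebra at that SPR, optionally
#' RT-corrected, segmented, and summarised by segment count and enrichment
#' scores.
#'
#' @param genome A `genome_model`.
#' @param spr_grid S-phase ratios to sweep.
#' @param composition_endpoints List of two [phase_composition()]s, high-SPR
#'   first. Defaults to S fractions 0.55 and 0.20.
#' @param mean_depth_grid Mean reads per bin per pool.
#' @param correction `"none"` or `"rt"`.
#' @param params [segmentation_params()].
#' @param n_cells Cells per simulated pool.
#' @param n_reps Replicates per grid cell.
#' @param rt_bin_width Stratum width for RT correction.
#' @param seed Integer seed.
#' @return data.frame with columns `spr`, `depth`, `rep`, `n_segments`,
#'   `es_gain`, `es_loss`, `seed`, sorted by (depth, spr, rep). ES values
#'   are `NA` when a replicate yields no gains or no losses.
#' @export
spr_sweep <- function(genome, spr_grid,
                      composition_endpoints = list(
                        phase_composition(0.30, 0.55, 0.15),
                        phase_composition(0.65, 0.20, 0.15)),
                      mean_depth_grid = 100,
                      correction = c("none", "rt"),
                      params = segmentation_params(),
                      n_cells = 200L,
                      n_reps = 1L,
                      rt_bin_width = 0.01,
                      seed = 1L) {
  stopifnot(inherits(genome, "genome_model"))
  correction <- match.arg(correction)
  if (length(spr_grid) == 0 || length(mean_depth_grid) == 0) stopf("empty grid")
  s_hi <- composition_endpoints[[1]]$s
  s_lo <- composition_endpoints[[2]]$s

  rows <- list()
  for (depth in sort(mean_depth_grid)) {
    for (spr in sort(spr_grid)) {
      for (rep in seq_len(n_reps)) {
        rep_seed <- derive_seed(seed, sprintf("sweep-%g-%g-%d", depth, spr, rep))
        pool_hi <- simulate_wgs_bins(genome, composition_endpoints[[1]],
                                     n_cells = n_cells, mean_depth = depth,
                                     seed = rep_seed)
        pool_lo <- simulate_wgs_bins(genome, composition_endpoints[[2]],
                                     n_cells = n_cells, mean_depth = depth,
                                     seed = rep_seed + 1L)
        sol <- solve_mixture_fractions(mixture_spec(
          s_esc = s_hi, s_mef = s_lo,
          rc_esc = sum(pool_hi$count), rc_mef = sum(pool_lo$count),
          s_ratio = spr))
        mixed <- mix_bin_counts(pool_hi, pool_lo, sol$x, sol$y, seed = rep_seed + 2L)
        if (correction == "rt") {
          mixed <- correct_by_covariate(mixed, genome$rt, kind = "rt",
                                        bin_width = rt_bin_width)$track
        }
        seg <- segment_track(depth_log2ratio(mixed, pseudocount = 1), genome, params)
        seg <- assign_rt(seg, genome)
        es <- tryCatch(enrichment_scores(seg), error = function(e) NULL)
        rows[[length(rows) + 1L]] <- data.frame(
          spr = spr, depth = depth, rep = rep, n_segments = nrow(seg),
          es_gain = if (is.null(es)) NA_real_ else es$es_gain,
          es_loss = if (is.null(es)) NA_real_ else es$es_loss,
          seed = rep_seed)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the SPR at which pseudo-CNV counts escalate
#'
#' A heuristic change-point estimate: the grid point maximising the second
#' difference of replicate-averaged segment counts (ties resolved to the
#' smallest SPR, with a warning when all second differences are equal).
#'
#' @param rows Output of [spr_sweep()] at a single depth.
#' @return The onset SPR (numeric scalar).
#' @export
onset_spr <- function(rows) {
  if (length(unique(rows$depth)) > 1) stopf("onset_spr expects rows at a single depth")
  avg <- tapply(rows$n_segments, rows$spr, mean)
  spr <- as.numeric(names(avg))
  if (length(spr) < 4) stopf("need at least 4 distinct SPR values")
  o <- order(spr)
  spr <- spr[o]; avg <- as.numeric(avg)[o]
  d2 <- diff(avg, differences = 2)  # second difference at interior points
  if (max(d2) - min(d2) < 1e-12) {
    warnf("flat second differences: onset is the smallest interior grid point")
    return(spr[2])
  }
  spr[1 + which.max(d2)]
}
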
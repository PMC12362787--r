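# Synthetic CpG methylome with a G1-vs-S methylation deficit concentrated
# at solo-WCGW sites (post-replication remethylation delay). Site geometry
# is constructed so the solo flag is consistent with the nearest-neighbour
# definition used by flag_solo(): solo sites sit alone, non-solo sites come
# in clusters closer than the solo window.

#' Simulate a two-phase CpG methylation table
#'
#' G1 methylated counts are `Binomial(coverage, base_level)`; S counts are
#' `Binomial(coverage, base_level * (1 - delay[context] * s))` with `s = 1`
#' at solo sites and `s = 0.5` at non-solo sites, so the expected G1 - S
#' methylation drop is `base_level * delay * s`.
#'
#' @param n_sites Number of CpG records.
#' @param context_mix Named fractions over `c(WCGW, SCGW, SCGS)` (sum 1).
#' @param solo_fraction Fraction of sites with no CpG neighbour within the
#'   solo window.
#' @param base_level Baseline methylation level in `[0, 1]`.
#' @param delay Named per-context fractional delay in `[0, 1]`.
#' @param coverage Read coverage per site and phase.
#' @param seed Integer seed.
#' @return data.frame with columns `chrom`, `pos` (0-based), `strand`,
#'   `context`, `solo`, `g1_meth`, `g1_total`, `s_meth`, `s_total`.
#' @export
simulate_methylome <- function(n_sites,
                               context_mix = c(WCGW = 0.4, SCGW = 0.4, SCGS = 0.2),
                               solo_fraction = 0.5,
                               base_level = 0.8,
                               delay = c(WCGW = 0.15, SCGW = 0.05, SCGS = 0),
                               coverage = 50L,
                               seed = 1L) {
  if (n_sites < 1) stopf("`n_sites` must be positive")
  if (coverage < 1) stopf("`coverage` must be >= 1")
  check_fraction(context_mix, "context_mix")
  check_fraction(solo_fraction, "solo_fraction")
  check_fraction(base_level, "base_level")
  if (any(delay < 0) || any(delay > 1)) stopf("`delay` entries must lie in [0, 1]")
  if (!all(c("WCGW", "SCGW", "SCGS") %in% names(delay))) {
    stopf("`delay` must name WCGW, SCGW and SCGS")
  }
  with_op_seed(seed, "methylome", {
    n_solo <- round(n_sites * solo_fraction)
    solo <- c(rep(TRUE, n_solo), rep(FALSE, n_sites - n_solo))

    # geometry: solo sites isolated; non-solo sites in pairs 50 bp apart
    # (a trailing odd non-solo site becomes a triple). Clusters separated by
    # 150-400 bp so no cross-cluster neighbour breaks a solo flag.
    pos <- integer(n_sites)
    cursor <- 500L
    i <- 1L
    while (i <= n_sites) {
      gap <- 150L + as.integer(stats::runif(1, 0, 250))
      if (solo[i] || i == n_sites) {
        pos[i] <- cursor
        cursor <- cursor + gap
        i <- i + 1L
      } else {
        pos[i] <- cursor
        pos[i + 1L] <- cursor + 50L
        cursor <- cursor + 50L + gap
        i <- i + 2L
      }
    }
    # a trailing lone "non-solo" would violate its flag; glue it to the
    # previous cluster instead
    if (!solo[n_sites] && (n_sites == 1L || pos[n_sites] - pos[n_sites - 1L] > 100L)) {
      if (n_sites == 1L) {
        solo[n_sites] <- TRUE
      } else {
        pos[n_sites] <- pos[n_sites - 1L] + 50L
        solo[n_sites - 1L] <- FALSE
      }
    }

    context <- sample(names(context_mix), n_sites, replace = TRUE, prob = context_mix)
    scaling <- ifelse(solo, 1, 0.5)
    p_s <- base_level * (1 - delay[context] * scaling)
    data.frame(
      chrom = "chr1",
      pos = pos,
      strand = "+",
      context = context,
      solo = solo,
      g1_meth = stats::rbinom(n_sites, coverage, base_level),
      g1_total = as.integer(coverage),
      s_meth = stats::rbinom(n_sites, coverage, p_s),
      s_total = as.integer(coverage),
      stringsAsFactors = FALSE
    )
  })
}
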
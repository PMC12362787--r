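# CpG context classification, solo flagging, G1-vs-S methylation-delay
# summaries, Fisher-based tiled DMR calling, promoter methylation and
# region overlap ratios.
#
# Context nomenclature: the two bases flanking a CpG are weak (W = A/T) or
# strong (S = C/G); WCGW has weak flanks on both sides, SCGS strong flanks
# on both sides, and SCGW covers the two mixed arrangements (SCGW and WCGS
# are reverse complements of each other, so a strand-symmetric CpG cannot
# distinguish them).

#' Classify the 4-base context of a CpG
#'
#' @param sequence DNA string (A/C/G/T).
#' @param pos 0-based position of the C of the CpG on the plus strand
#'   (BED-style, matching the `pos` column of methylation tables).
#' @return `"WCGW"`, `"SCGW"` or `"SCGS"`.
#' @export
classify_cpg_context <- function(sequence, pos) {
  n <- nchar(sequence)
  if (pos < 1 || pos + 3 > n) {
    if (substr(sequence, pos + 1, pos + 2) != "CG") stopf("no CpG at position %d", pos)
    stopf("unclassifiable: flank out of range at position %d", pos)
  }
  if (substr(sequence, pos + 1, pos + 2) != "CG") stopf("no CpG at position %d", pos)
  left <- substr(sequence, pos, pos)
  right <- substr(sequence, pos + 3, pos + 3)
  cls <- function(b) {
    if (b %in% c("A", "T")) "W" else if (b %in% c("C", "G")) "S"
    else stopf("unclassifiable: ambiguous base '%s'", b)
  }
  key <- paste0(cls(left), cls(right))
  switch(key, WW = "WCGW", SS = "SCGS", "SCGW")
}

#' Flag solo CpGs
#'
#' A CpG is solo when no other CpG position lies within `window` bp of it
#' (nearest-neighbour distance strictly greater than `window`; a distance
#' of exactly `window` breaks the flag).
#'
#' @param positions Sorted unique integer CpG positions on one chromosome.
#' @param window Isolation window in bp (default 100).
#' @return Logical vector, one flag per position.
#' @export
flag_solo <- function(positions, window = 100L) {
  if (length(positions) == 0) return(logical(0))
  if (is.unsorted(positions, strictly = TRUE)) stopf("positions must be sorted and unique")
  d_prev <- c(Inf, diff(positions))
  d_next <- c(diff(positions), Inf)
  d_prev > window & d_next > window
}

#' Per-context G1-minus-S methylation-delay summary
#'
#' For every site with both phase totals at least `min_total`, the per-site
#' difference `g1_meth/g1_total - s_meth/s_total` is computed; each context
#' is summarised by the mean difference, its standard error, and a
#' two-sided one-sample t test against zero.
#'
#' @param records Methylation data.frame as produced by
#'   [simulate_methylome()] (columns `context`, `solo`, `g1_meth`,
#'   `g1_total`, `s_meth`, `s_total`).
#' @param min_total Minimum coverage per phase (default 5).
#' @param solo_only Restrict to solo-flagged sites.
#' @return data.frame with one row per context: `context`, `n`,
#'   `mean_diff`, `se`, `t`, `p` (NA rows for contexts with < 2 sites).
#' @export
phase_delay_summary <- function(records, min_total = 5L, solo_only = FALSE) {
  keep <- records$g1_total >= min_total & records$s_total >= min_total
  if (solo_only) keep <- keep & records$solo
  rec <- records[keep, , drop = FALSE]
  diffs <- rec$g1_meth / rec$g1_total - rec$s_meth / rec$s_total
  do.call(rbind, lapply(c("WCGW", "SCGW", "SCGS"), function(ctx) {
    d <- diffs[rec$context == ctx]
    if (length(d) < 2) {
      return(data.frame(context = ctx, n = length(d), mean_diff = NA_real_,
                        se = NA_real_, t = NA_real_, p = NA_real_))
    }
    se <- stats::sd(d) / sqrt(length(d))
    if (se == 0) {
      warnf("context %s has zero variance; t undefined", ctx)
      return(data.frame(context = ctx, n = length(d), mean_diff = mean(d),
                        se = 0, t = NA_real_, p = if (mean(d) == 0) 1 else NA_real_))
    }
    tt <- stats::t.test(d, mu = 0)
    data.frame(context = ctx, n = length(d), mean_diff = mean(d), se = se,
               t = unname(tt$statistic), p = tt$p.value, stringsAsFactors = FALSE)
  }))
}

#' Call differentially methylated regions on fixed tiles
#'
#' CpGs are grouped into fixed `tile_size` tiles per chromosome;
#' methylated/total counts are pooled per tile and side, tested with a
#' two-sided Fisher exact test, corrected by Benjamini-Hochberg, and a tile
#' is a DMR when the pooled difference (target minus reference, percentage
#' points) exceeds `diff_min` in absolute value and `q < q_max`.
#'
#' @param records Methylation data.frame with `chrom`, `pos` and the count
#'   columns named `<side>_meth` / `<side>_total`.
#' @param target,reference Side prefixes, e.g. `"s"` and `"g1"`.
#' @param tile_size Tile width in bp (default 1000).
#' @param diff_min Minimum absolute pooled difference in percentage points
#'   (default 30, strict).
#' @param q_max FDR threshold (default 0.01).
#' @param min_cpg Minimum covered CpGs per tile (default 3).
#' @return data.frame of DMRs (`chrom`, `start`, `end`, `diff`, `p`, `q`,
#'   `direction`, `n_cpg`); the full per-tile table is attached as
#'   attribute `"tiles"`.
#' @export
call_dmrs <- function(records, target = "s", reference = "g1",
                      tile_size = 1000L, diff_min = 30, q_max = 0.01,
                      min_cpg = 3L) {
  tm <- records[[paste0(target, "_meth")]]; tt <- records[[paste0(target, "_total")]]
  rm_ <- records[[paste0(reference, "_meth")]]; rt <- records[[paste0(reference, "_total")]]
  if (is.null(tm) || is.null(rm_)) stopf("missing count columns for the requested sides")
  tile <- paste0(records$chrom, ":", records$pos %/% tile_size)
  agg <- data.frame(
    tile = tile, chrom = records$chrom,
    start = (records$pos %/% tile_size) * tile_size,
    tm = tm, tt = tt, rm = rm_, rt = rt
  )
  g <- split(agg, agg$tile)
  rows <- lapply(g, function(d) {
    if (nrow(d) < min_cpg) return(NULL)
    TT <- sum(d$tt); RT <- sum(d$rt)
    if (TT == 0 || RT == 0) return(NULL)
    TM <- sum(d$tm); RM <- sum(d$rm)
    p <- stats::fisher.test(matrix(c(TM, TT - TM, RM, RT - RM), nrow = 2))$p.value
    data.frame(chrom = d$chrom[1], start = d$start[1], end = d$start[1] + tile_size,
               diff = (TM / TT - RM / RT) * 100, p = p, n_cpg = nrow(d),
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (length(rows) == 0) {
    out <- data.frame(chrom = character(0), start = integer(0), end = integer(0),
                      diff = numeric(0), p = numeric(0), q = numeric(0),
                      direction = character(0), n_cpg = integer(0))
    attr(out, "tiles") <- out
    return(out)
  }
  tiles <- do.call(rbind, rows)
  tiles <- tiles[order(tiles$chrom, tiles$start), , drop = FALSE]
  tiles$q <- stats::p.adjust(tiles$p, method = "BH")
  tiles$direction <- ifelse(tiles$diff > 0, "hyper", "hypo")
  tiles$is_dmr <- abs(tiles$diff) > diff_min & tiles$q < q_max
  rownames(tiles) <- NULL
  out <- tiles[tiles$is_dmr, c("chrom", "start", "end", "diff", "p", "q", "direction", "n_cpg"),
               drop = FALSE]
  rownames(out) <- NULL
  attr(out, "tiles") <- tiles
  out
}

#' Promoter methylation levels per gene
#'
#' The promoter is `[TSS - 2000, TSS + 500)` for plus-strand genes and the
#' strand mirror `[end - 500, end + 2000)` for minus-strand genes. The
#' reported level is the mean of per-site `meth/total` over covered CpGs;
#' genes covering fewer than `min_cpg` sites are reported with `NA`.
#'
#' @param genes data.frame with `gene`, `chrom`, `start`, `end`, `strand`.
#' @param records Methylation data.frame with `chrom`, `pos` and count
#'   columns for each side in `sides`.
#' @param min_cpg Minimum covered CpGs per gene (default 10).
#' @param sides Side prefixes to summarise (default `c("g1", "s")`).
#' @param upstream,downstream Promoter extent around the TSS in bp.
#' @return data.frame with `gene`, `n_cpg` and one `<side>_level` column
#'   per side.
#' @export
promoter_methylation <- function(genes, records, min_cpg = 10L,
                                 sides = c("g1", "s"),
                                 upstream = 2000L, downstream = 500L) {
  need <- c("gene", "chrom", "start", "end", "strand")
  if (!all(need %in% names(genes))) stopf("malformed gene annotation")
  if (!all(genes$strand %in% c("+", "-"))) stopf("gene strand must be '+' or '-'")
  out <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    prom <- if (g$strand == "+") c(g$start - upstream, g$start + downstream)
            else c(g$end - downstream, g$end + upstream)
    hit <- records$chrom == g$chrom & records$pos >= prom[1] & records$pos < prom[2]
    n <- sum(hit)
    row <- data.frame(gene = g$gene, n_cpg = n, stringsAsFactors = FALSE)
    for (s in sides) {
      lv <- if (n >= min_cpg) {
        mean(records[[paste0(s, "_meth")]][hit] / records[[paste0(s, "_total")]][hit])
      } else NA_real_
      row[[paste0(s, "_level")]] <- lv
    }
    row
  })
  do.call(rbind, out)
}

#' Fraction of query bases overlapped by a subject interval set
#'
#' @param query,subject data.frames of `chrom`, `start`, `end` (0-based
#'   half-open).
#' @return `sum(bp of query covered by subject) / sum(bp of query)`.
#' @export
region_overlap_ratio <- function(query, subject) {
  if (nrow(query) == 0) stopf("empty query")
  qg <- gr_from_intervals(query)
  if (nrow(subject) == 0) return(0)
  sg <- GenomicRanges::reduce(gr_from_intervals(subject))
  ov <- sum(GenomicRanges::width(GenomicRanges::intersect(GenomicRanges::reduce(qg), sg)))
  ov / sum(query$end - query$start)
}
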
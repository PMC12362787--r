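# Differential expression with and without cell-cycle phasing. The test is
# a two-part hurdle: a 1-df likelihood-ratio statistic on the detection rate
# (logistic detection ~ group, equivalent to the 2x2 G test) plus a 1-df
# likelihood-ratio statistic on log2(CPM + 1) among detected cells (normal
# model, group mean vs pooled mean), summed into a chi-square whose degrees
# of freedom count the contributing components. P-values are corrected by
# Benjamini-Hochberg across genes.

#' Filter cells by mitochondrial fraction and genes by detection rate
#'
#' Cells with `mito_fraction > max_mito` are removed first; genes detected
#' (`count > 0`) in fewer than `min_expr_frac` of the remaining cells are
#' removed second (boundary inclusive: exactly the threshold is kept).
#'
#' @param data An `expression_dataset`.
#' @param min_expr_frac Minimum detection fraction for a gene (default 0.05).
#' @param max_mito Maximum tolerated mitochondrial fraction per cell.
#' @return The filtered `expression_dataset`.
#' @export
qc_filter <- function(data, min_expr_frac = 0.05, max_mito = 0.2) {
  stopifnot(inherits(data, "expression_dataset"))
  check_fraction(c(min_expr_frac, max_mito), "thresholds")
  keep_cells <- data$cell_meta$mito_fraction <= max_mito
  if (!any(keep_cells)) stopf("all cells removed by the mitochondrial filter")
  counts <- data$counts[, keep_cells, drop = FALSE]
  meta <- data$cell_meta[keep_cells, , drop = FALSE]
  det_frac <- rowMeans(counts > 0)
  keep_genes <- det_frac >= min_expr_frac
  if (!any(keep_genes)) stopf("all genes removed by the detection filter")
  expression_dataset(counts[keep_genes, , drop = FALSE], meta,
                     gene_ids = data$gene_ids[keep_genes])
}

# x*log(x/e) with the 0*log0 = 0 convention
xlogx <- function(x, e) ifelse(x > 0, x * log(x / e), 0)

#' Two-part hurdle differential expression test
#'
#' @param data An `expression_dataset`.
#' @param cells_a,cells_b Cell ids (or logical/integer indices) of the two
#'   groups; fold change is reported as B over A.
#' @param fc_epsilon Stabiliser added to group mean CPM for the fold change.
#' @return data.frame with one row per gene: `gene`, `fold_change`, `p`,
#'   `fdr`, `direction`, `phase` (set to `"pooled"`; callers re-label).
#' @export
hurdle_de <- function(data, cells_a, cells_b, fc_epsilon = 0.1) {
  stopifnot(inherits(data, "expression_dataset"))
  ia <- if (is.character(cells_a)) match(cells_a, colnames(data$counts)) else (seq_len(ncol(data$counts)))[cells_a]
  ib <- if (is.character(cells_b)) match(cells_b, colnames(data$counts)) else (seq_len(ncol(data$counts)))[cells_b]
  if (anyNA(ia) || anyNA(ib)) stopf("unknown cell id")
  if (length(ia) < 3 || length(ib) < 3) stopf("need at least 3 cells per side")

  counts <- data$counts
  y <- log2_cpm(counts)
  cpm <- 2^y - 1
  det <- counts > 0

  na <- length(ia); nb <- length(ib)
  ka <- rowSums(det[, ia, drop = FALSE]); kb <- rowSums(det[, ib, drop = FALSE])
  present <- (ka + kb) > 0
  if (any(!present)) warnf("%d gene(s) detected nowhere were skipped", sum(!present))

  # detection component: 2x2 likelihood-ratio (G) statistic, 1 df
  p_pool <- (ka + kb) / (na + nb)
  g_det <- 2 * (xlogx(ka, na * p_pool) + xlogx(na - ka, na * (1 - p_pool)) +
                xlogx(kb, nb * p_pool) + xlogx(nb - kb, nb * (1 - p_pool)))

  # continuous component among detected cells: normal LRT, 1 df when both
  # sides have >= 2 detected cells
  mask_a <- det[, ia, drop = FALSE]; mask_b <- det[, ib, drop = FALSE]
  ya <- y[, ia, drop = FALSE]; yb <- y[, ib, drop = FALSE]
  sa <- rowSums(ya * mask_a); sb <- rowSums(yb * mask_b)
  qa <- rowSums(ya^2 * mask_a); qb <- rowSums(yb^2 * mask_b)
  eligible <- ka >= 2 & kb >= 2
  mean_a <- ifelse(ka > 0, sa / ka, 0); mean_b <- ifelse(kb > 0, sb / kb, 0)
  rss1 <- (qa - ka * mean_a^2) + (qb - kb * mean_b^2)
  ntot <- ka + kb
  mean_t <- ifelse(ntot > 0, (sa + sb) / ntot, 0)
  rss0 <- (qa + qb) - ntot * mean_t^2
  g_cont <- ifelse(eligible & rss0 > 0,
                   ntot * log(pmax(rss0, 1e-12) / pmax(rss1, 1e-12)), 0)
  g_cont <- pmax(g_cont, 0)

  df <- 1 + as.integer(eligible)
  stat <- g_det + g_cont
  p <- stats::pchisq(stat, df = df, lower.tail = FALSE)

  # fold change on the CPM scale over all group cells, pseudo-stabilised
  fc <- (rowMeans(cpm[, ib, drop = FALSE]) + fc_epsilon) /
        (rowMeans(cpm[, ia, drop = FALSE]) + fc_epsilon)

  res <- data.frame(gene = data$gene_ids, fold_change = fc, p = p,
                    stringsAsFactors = FALSE)
  res <- res[present, , drop = FALSE]
  res$fdr <- stats::p.adjust(res$p, method = "BH")
  res$direction <- ifelse(res$fold_change > 1, "up", "down")
  res$phase <- "pooled"
  rownames(res) <- NULL
  res
}

de_threshold <- function(res, fc_min, fdr_max) {
  res[(res$fold_change >= fc_min | res$fold_change <= 1 / fc_min) &
        res$fdr < fdr_max, , drop = FALSE]
}

#' Direct (pooled) two-group differential expression
#'
#' Runs the hurdle test on all group-A vs all group-B cells and keeps genes
#' with fold change `>= fc_min` or `<= 1/fc_min` (boundary inclusive) and
#' `fdr < fdr_max`.
#'
#' @param data An `expression_dataset` with a `group` column in `cell_meta`.
#' @param fc_min Ratio threshold (default 2, i.e. |log2FC| >= 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return data.frame of significant records (`phase = "pooled"`).
#' @export
direct_comparison <- function(data, fc_min = 2, fdr_max = 0.05) {
  stopifnot(inherits(data, "expression_dataset"))
  a <- data$cell_meta$cell[data$cell_meta$group == "A"]
  b <- data$cell_meta$cell[data$cell_meta$group == "B"]
  if (length(a) == 0 || length(b) == 0) stopf("both groups must be non-empty")
  de_threshold(hurdle_de(data, a, b), fc_min, fdr_max)
}

#' Phase-stratified differential expression with merged calls
#'
#' The hurdle test is run within every phase where both groups have at
#' least `min_cells_per_side` cells; thresholds are applied per phase and
#' the merged set is the union of per-phase significant genes. Genes
#' significant in two or more phases with opposite directions are flagged
#' discordant and excluded from the merged set (retained in provenance).
#'
#' @param data An `expression_dataset` with `phase` and `group` metadata.
#' @param fc_min,fdr_max Thresholds as in [direct_comparison()].
#' @param min_cells_per_side Minimum cells per group within a phase.
#' @return List with `per_phase` (named list of significant data.frames),
#'   `merged` (data.frame with a `phases` provenance column), `discordant`
#'   (gene ids) and `ineligible_phases`.
#' @export
phase_comparison <- function(data, fc_min = 2, fdr_max = 0.05, min_cells_per_side = 3L) {
  stopifnot(inherits(data, "expression_dataset"))
  meta <- data$cell_meta
  per_phase <- list(); ineligible <- character(0)
  for (p in PHASES) {
    a <- meta$cell[meta$group == "A" & meta$phase == p]
    b <- meta$cell[meta$group == "B" & meta$phase == p]
    if (length(a) < min_cells_per_side || length(b) < min_cells_per_side) {
      ineligible <- c(ineligible, p)
      next
    }
    res <- de_threshold(hurdle_de(data, a, b), fc_min, fdr_max)
    res$phase <- p
    per_phase[[p]] <- res
  }
  if (length(per_phase) == 0) stopf("no phase has enough cells on both sides")

  all_sig <- do.call(rbind, per_phase)
  prov <- tapply(all_sig$phase, all_sig$gene, paste, collapse = ",")
  dirs <- tapply(all_sig$direction, all_sig$gene, function(d) length(unique(d)))
  discordant <- names(dirs)[dirs > 1]
  merged_genes <- setdiff(names(prov), discordant)
  merged <- all_sig[!duplicated(all_sig$gene) & all_sig$gene %in% merged_genes, , drop = FALSE]
  merged$phases <- as.character(prov[merged$gene])
  rownames(merged) <- NULL
  list(per_phase = per_phase, merged = merged,
       discordant = discordant, ineligible_phases = ineligible)
}

#' Partition two gene sets into a Venn layout
#'
#' @param a,b Character gene sets.
#' @return List with `only_a`, `only_b`, `shared`.
#' @export
compare_de_sets <- function(a, b) {
  a <- unique(a); b <- unique(b)
  list(only_a = setdiff(a, b), only_b = setdiff(b, a), shared = intersect(a, b))
}

#' Control-matched gene-set signature scores
#'
#' Genes are binned into `n_bins` expression-matched bins by their average
#' `log2(CPM + 1)`; each signature gene is compared against `n_control`
#' genes sampled (seeded) from its own bin, and a cell's score for a set is
#' the mean over set genes of (gene expression - mean control expression).
#'
#' @param data An `expression_dataset`.
#' @param gene_sets Named list of gene-id vectors.
#' @param n_bins Number of average-expression bins (default 25).
#' @param n_control Control genes per signature gene (default 100, sampled
#'   with replacement when a bin is smaller).
#' @param seed Integer seed.
#' @return Numeric matrix, cells x sets.
#' @export
signature_scores <- function(data, gene_sets, n_bins = 25L, n_control = 100L, seed = 1L) {
  stopifnot(inherits(data, "expression_dataset"))
  y <- log2_cpm(data$counts)
  avg <- rowMeans(y)
  bin <- ceiling(rank(avg, ties.method = "first") / (length(avg) / n_bins))
  scores <- matrix(NA_real_, nrow = ncol(y), ncol = length(gene_sets),
                   dimnames = list(colnames(y), names(gene_sets)))
  for (si in seq_along(gene_sets)) {
    gs <- intersect(gene_sets[[si]], rownames(y))
    if (length(gs) == 0) stopf("gene set '%s' has no gene present", names(gene_sets)[si])
    per_gene <- with_op_seed(seed, paste0("sig-", names(gene_sets)[si]), {
      vapply(gs, function(g) {
        pool <- which(bin == bin[g] & rownames(y) != g)
        if (length(pool) == 0) pool <- which(rownames(y) != g)
        ctrl <- sample(pool, n_control, replace = length(pool) < n_control)
        y[g, ] - colMeans(y[ctrl, , drop = FALSE])
      }, numeric(ncol(y)))
    })
    scores[, si] <- rowMeans(per_gene)
  }
  scores
}
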
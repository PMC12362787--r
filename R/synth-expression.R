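# Synthetic phase-structured single-cell expression. The generator plants
# two kinds of signal: per-gene phase effects (cell-cycle genes whose mean
# depends on the phase a cell is in) and per-gene group effects (true
# biological differences between groups A and B). Under unequal phase
# compositions the former confound a pooled two-group comparison.

#' Construct an expression simulation design
#'
#' @param n_genes Number of genes.
#' @param cells_per_group_per_phase Matrix of cell counts with rownames
#'   `c("A","B")` and colnames `c("G1","S","G2M")`.
#' @param phase_effect `n_genes x 3` matrix of positive multipliers
#'   (columns G1, S, G2M); a row of ones is a cell-cycle-neutral gene.
#' @param group_log2fc Per-gene log2 fold change applied to group B.
#' @param baseline_mean Per-gene positive baseline mean count.
#' @param dispersion Negative-binomial dispersion (var = mu + dispersion*mu^2).
#' @param dropout_midpoint,dropout_slope Logistic detection model on
#'   `log(mu + 1)`: detection probability
#'   `plogis(dropout_slope * (log(mu + 1) - dropout_midpoint))`.
#' @param marker_genes Named list of disjoint gene-id vectors per phase
#'   (names among `G1`, `S`, `G2M`); optional.
#' @param seed Integer seed.
#' @return An object of class `expression_design`.
#' @export
expression_design <- function(n_genes,
                              cells_per_group_per_phase,
                              phase_effect = NULL,
                              group_log2fc = NULL,
                              baseline_mean = NULL,
                              dispersion = 0.4,
                              dropout_midpoint = 1,
                              dropout_slope = 1.5,
                              marker_genes = list(),
                              seed = 1L) {
  if (n_genes < 1) stopf("empty design: need n_genes >= 1")
  cells <- as.matrix(cells_per_group_per_phase)
  if (!all(rownames(cells) %in% c("A", "B")) || !all(colnames(cells) %in% c("G1", "S", "G2M"))) {
    stopf("cell count matrix needs rownames in {A,B} and colnames in {G1,S,G2M}")
  }
  if (any(cells < 0)) stopf("cell counts must be >= 0")
  if (sum(cells) < 1) stopf("empty design: no cells")
  if (dispersion <= 0) stopf("dispersion must be positive")
  if (is.null(phase_effect)) phase_effect <- matrix(1, n_genes, 3)
  phase_effect <- as.matrix(phase_effect)
  colnames(phase_effect) <- c("G1", "S", "G2M")
  if (nrow(phase_effect) != n_genes || any(phase_effect <= 0)) {
    stopf("phase_effect must be a positive n_genes x 3 matrix")
  }
  if (is.null(group_log2fc)) group_log2fc <- rep(0, n_genes)
  if (is.null(baseline_mean)) baseline_mean <- rep(5, n_genes)
  if (length(group_log2fc) != n_genes || length(baseline_mean) != n_genes) {
    stopf("per-gene parameter length mismatch")
  }
  if (any(baseline_mean <= 0)) stopf("baseline_mean must be positive")
  if (length(marker_genes) > 1) {
    ids <- unlist(marker_genes, use.names = FALSE)
    if (anyDuplicated(ids)) stopf("marker sets must be disjoint")
  }
  structure(list(
    n_genes = as.integer(n_genes), cells = cells, phase_effect = phase_effect,
    group_log2fc = as.numeric(group_log2fc), baseline_mean = as.numeric(baseline_mean),
    dispersion = dispersion, dropout_midpoint = dropout_midpoint,
    dropout_slope = dropout_slope, marker_genes = marker_genes,
    seed = as.integer(seed)
  ), class = "expression_design")
}

#' Construct a gene x cell expression dataset
#'
#' @param counts Non-negative integer matrix, genes in rows, cells in columns.
#' @param cell_meta data.frame with one row per cell and columns `cell`,
#'   `phase` (G1/S/G2M), `group` (A/B) and `mito_fraction`.
#' @param gene_ids Character gene identifiers (defaults to rownames).
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(counts, cell_meta, gene_ids = rownames(counts)) {
  counts <- as.matrix(counts)
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(nrow(counts)))
  if (anyDuplicated(gene_ids)) stopf("duplicate gene ids")
  if (anyDuplicated(cell_meta$cell)) stopf("duplicate cell ids")
  if (nrow(cell_meta) != ncol(counts)) stopf("cell_meta rows must match columns of counts")
  if (any(counts < 0)) stopf("counts must be non-negative")
  rownames(counts) <- gene_ids
  colnames(counts) <- cell_meta$cell
  structure(list(counts = counts, cell_meta = cell_meta, gene_ids = gene_ids),
            class = "expression_dataset")
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf("expression_dataset: %d genes x %d cells (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s:%d", names(table(x$cell_meta$phase)),
                            as.integer(table(x$cell_meta$phase))), collapse = " ")))
  invisible(x)
}

#' Simulate a phase-structured expression dataset
#'
#' Counts are negative binomial with mean
#' `baseline_mean * phase_effect[phase] * 2^(group_log2fc * [group == B])`,
#' thinned by a logistic-in-log-mean detection (dropout) model. Cell-level
#' mitochondrial fractions are drawn from a Beta(2, 38) (about 5 percent) so
#' QC filters are exercised.
#'
#' @param design An [expression_design()].
#' @return An [expression_dataset()] with truth columns in `cell_meta`.
#' @export
simulate_expression <- function(design) {
  stopifnot(inherits(design, "expression_design"))
  with_op_seed(design$seed, "expr", {
    groups <- rownames(design$cells)
    phases <- colnames(design$cells)
    meta <- do.call(rbind, lapply(groups, function(g) {
      do.call(rbind, lapply(phases, function(p) {
        k <- design$cells[g, p]
        if (k == 0) return(NULL)
        data.frame(phase = rep(p, k), group = rep(g, k), stringsAsFactors = FALSE)
      }))
    }))
    n_cells <- nrow(meta)
    meta$cell <- sprintf("cell%04d", seq_len(n_cells))
    meta$mito_fraction <- stats::rbeta(n_cells, 2, 38)
    meta <- meta[, c("cell", "phase", "group", "mito_fraction")]

    pe <- design$phase_effect[, meta$phase, drop = FALSE]       # genes x cells
    mu <- design$baseline_mean * pe *
      2^(outer(design$group_log2fc, as.numeric(meta$group == "B")))
    counts <- matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / design$dispersion),
                     nrow = design$n_genes)
    p_det <- stats::plogis(design$dropout_slope * (log(mu + 1) - design$dropout_midpoint))
    keep <- matrix(stats::rbinom(length(mu), 1, p_det), nrow = design$n_genes)
    counts <- counts * keep
    ds <- expression_dataset(counts, meta, gene_ids = paste0("gene", seq_len(design$n_genes)))
    ds$design <- design
    ds
  })
}
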
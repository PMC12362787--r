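# Cell-cycle phase assignment: correlation-based augmentation of marker
# gene sets, a transparent z-score argmax classifier, and one-vs-rest
# precision / sensitivity / F1 evaluation with optional resampling.

PHASES <- c("G1", "S", "G2M")

#' Construct marker gene sets
#'
#' @param g1,s,g2m Character vectors of gene ids (a gene may appear in at
#'   most one set).
#' @param source `"base"` or `"augmented"`.
#' @param dropped data.frame of `(gene, r)` excluded by the correlation
#'   filter (populated by [augment_marker_set()]).
#' @return An object of class `marker_sets`.
#' @export
marker_sets <- function(g1 = character(0), s = character(0), g2m = character(0),
                        source = "base",
                        dropped = data.frame(gene = character(0), r = numeric(0))) {
  g1 <- unique(g1); s <- unique(s); g2m <- unique(g2m)
  if (anyDuplicated(c(g1, s, g2m))) stopf("a gene may appear in at most one phase set")
  structure(list(g1 = g1, s = s, g2m = g2m, source = source, dropped = dropped),
            class = "marker_sets")
}

#' @export
print.marker_sets <- function(x, ...) {
  cat(sprintf("marker_sets (%s): G1 %d, S %d, G2M %d genes; %d dropped\n",
              x$source, length(x$g1), length(x$s), length(x$g2m), nrow(x$dropped)))
  invisible(x)
}

log2_cpm <- function(counts) {
  lib <- colSums(counts)
  lib[lib == 0] <- 1
  log2(t(t(counts) / lib * 1e6) + 1)
}

#' Average expression profile per cell-cycle phase
#'
#' Per-gene mean of `log2(CPM + 1)` within each labelled phase.
#'
#' @param expr An `expression_dataset`.
#' @param labels Per-cell phase labels in `{G1, S, G2M}`.
#' @return Numeric matrix, genes x 3 (columns G1, S, G2M).
#' @export
average_phase_profiles <- function(expr, labels = expr$cell_meta$phase) {
  stopifnot(inherits(expr, "expression_dataset"))
  if (length(labels) != ncol(expr$counts)) stopf("label length mismatch")
  tab <- table(factor(labels, levels = PHASES))
  if (any(tab < 2)) stopf("every phase needs at least 2 labelled cells")
  y <- log2_cpm(expr$counts)
  prof <- vapply(PHASES, function(p) rowMeans(y[, labels == p, drop = FALSE]),
                 numeric(nrow(y)))
  rownames(prof) <- expr$gene_ids
  prof
}

#' Augment marker sets by correlation with phase templates
#'
#' Every gene not already in the base sets is scored by the Pearson
#' correlation between its 3-point per-phase mean profile and each phase's
#' standardised one-hot template; the gene joins the phase of its maximal
#' correlation when `r >= r_min` and is recorded as dropped (weak)
#' otherwise. Flat genes, whose correlation is undefined, are dropped.
#'
#' @param expr An `expression_dataset`.
#' @param labels Per-cell phase labels.
#' @param base A [marker_sets()] to extend (conflicts resolve to base).
#' @param r_min Minimum correlation for inclusion (default 0.1, boundary
#'   inclusive).
#' @return A [marker_sets()] with `source = "augmented"`.
#' @export
augment_marker_set <- function(expr, labels = expr$cell_meta$phase,
                               base = marker_sets(), r_min = 0.1) {
  stopifnot(inherits(expr, "expression_dataset"), inherits(base, "marker_sets"))
  if (nrow(expr$counts) == 0) stopf("empty expression dataset")
  prof <- average_phase_profiles(expr, labels)
  in_base <- unlist(base[c("g1", "s", "g2m")], use.names = FALSE)
  candidates <- setdiff(rownames(prof), in_base)
  templates <- diag(3)  # one column per phase; cor() standardises internally
  added <- list(G1 = character(0), S = character(0), G2M = character(0))
  dropped <- list()
  for (g in candidates) {
    v <- prof[g, ]
    if (stats::sd(v) == 0) {
      dropped[[length(dropped) + 1L]] <- data.frame(gene = g, r = NA_real_)
      next
    }
    rs <- apply(templates, 2, function(tmpl) stats::cor(v, tmpl))
    best <- which.max(rs)
    if (rs[best] >= r_min) {
      added[[best]] <- c(added[[best]], g)
    } else {
      dropped[[length(dropped) + 1L]] <- data.frame(gene = g, r = rs[best])
    }
  }
  marker_sets(
    g1 = c(base$g1, added$G1), s = c(base$s, added$S), g2m = c(base$g2m, added$G2M),
    source = "augmented",
    dropped = if (length(dropped)) do.call(rbind, dropped)
              else data.frame(gene = character(0), r = numeric(0))
  )
}

#' Assign cell-cycle phases by marker z-score argmax
#'
#' Each phase score is the mean, over that phase's marker genes present in
#' the data, of the per-gene z-scored `log2(CPM + 1)`; the call is the
#' argmax with ties broken in the order G1 < S < G2M (warned).
#'
#' @param expr An `expression_dataset`.
#' @param markers A [marker_sets()] with at least one present gene per set.
#' @return data.frame with columns `cell`, `g1_score`, `s_score`,
#'   `g2m_score`, `label`.
#' @export
assign_phases <- function(expr, markers) {
  stopifnot(inherits(expr, "expression_dataset"), inherits(markers, "marker_sets"))
  y <- log2_cpm(expr$counts)
  mu <- rowMeans(y)
  sdv <- apply(y, 1, stats::sd)
  z <- (y - mu) / ifelse(sdv > 0, sdv, 1)
  sets <- list(G1 = markers$g1, S = markers$s, G2M = markers$g2m)
  scores <- vapply(sets, function(gs) {
    gs <- intersect(gs, rownames(y))
    if (length(gs) == 0) stopf("a marker set has no gene present in the data")
    colMeans(z[gs, , drop = FALSE])
  }, numeric(ncol(y)))
  if (ncol(expr$counts) == 1) scores <- matrix(scores, nrow = 1, dimnames = list(NULL, PHASES))
  ties <- apply(scores, 1, function(s) sum(s == max(s)) > 1)
  if (any(ties)) warnf("%d cell(s) with tied phase scores assigned by G1 < S < G2M order",
                       sum(ties))
  label <- PHASES[apply(scores, 1, which.max)]  # which.max takes first: G1 < S < G2M
  data.frame(cell = expr$cell_meta$cell,
             g1_score = scores[, "G1"], s_score = scores[, "S"],
             g2m_score = scores[, "G2M"], label = label,
             stringsAsFactors = FALSE)
}

phase_confusion_metrics <- function(pred, truth) {
  per <- do.call(rbind, lapply(PHASES, function(p) {
    tp <- sum(pred == p & truth == p)
    fp <- sum(pred == p & truth != p)
    fn <- sum(pred != p & truth == p)
    precision <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
    sensitivity <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
    f1 <- if (!is.na(precision) && !is.na(sensitivity) && precision + sensitivity > 0) {
      2 * sensitivity * precision / (sensitivity + precision)
    } else NA_real_
    data.frame(phase = p, tp = tp, fp = fp, fn = fn,
               precision = precision, sensitivity = sensitivity, f1 = f1,
               stringsAsFactors = FALSE)
  }))
  if (any(is.na(per$precision))) {
    warnf("phase(s) with no predictions: precision undefined, excluded from macro F1")
  }
  list(per_phase = per, macro_f1 = mean(per$f1, na.rm = TRUE))
}

#' Evaluate phase calls against ground truth
#'
#' One-vs-rest TP/FP/FN per phase with precision `TP/(TP+FP)`, sensitivity
#' `TP/(TP+FN)` and their harmonic-mean F1; the macro F1 averages defined
#' per-phase F1 values. With `resample_frac < 1` the metrics are computed on
#' `n_reps` seeded random subsamples of the cells.
#'
#' @param pred,truth Equal-length label vectors in `{G1, S, G2M}`.
#' @param resample_frac Fraction of cells per evaluation replicate.
#' @param n_reps Number of resampling replicates.
#' @param seed Integer seed for the resampling.
#' @return List with `per_phase` (data.frame with a `rep` column) and
#'   `macro_f1` (per-rep numeric vector).
#' @export
evaluate_phasing <- function(pred, truth, resample_frac = 1.0, n_reps = 1L, seed = 1L) {
  if (length(pred) != length(truth)) stopf("length mismatch")
  if (!all(pred %in% PHASES) || !all(truth %in% PHASES)) stopf("labels must be G1, S or G2M")
  check_fraction(resample_frac, "resample_frac")
  n <- length(pred)
  reps <- lapply(seq_len(n_reps), function(r) {
    idx <- if (resample_frac < 1) {
      with_op_seed(seed, sprintf("phase-eval-%d", r),
                   sample.int(n, max(1L, floor(resample_frac * n))))
    } else seq_len(n)
    m <- phase_confusion_metrics(pred[idx], truth[idx])
    m$per_phase$rep <- r
    m
  })
  list(per_phase = do.call(rbind, lapply(reps, `[[`, "per_phase")),
       macro_f1 = vapply(reps, `[[`, 0, "macro_f1"))
}
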
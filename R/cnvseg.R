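# CNV calling on log2 depth ratios, replication-timing annotation of calls,
# and the gain-in-early / loss-in-late enrichment statistics.

#' Segmentation parameters
#'
#' @param log2_cutoff Absolute log2-ratio threshold for calling a bin (and a
#'   segment mean) gained or lost. 0.25 is the conventional read-depth CNV
#'   threshold.
#' @param min_length Minimum segment length in bp; segments of length
#'   `<= min_length` are dropped (strict).
#' @param max_neutral_gap_bins Number of neutral bins allowed to bridge two
#'   same-class runs under `run_merge`.
#' @param method `"run_merge"` (deterministic run merging, the default) or
#'   `"recursive_split"` (recursive binary segmentation with a permutation
#'   stopping rule, then thresholding of segment means).
#' @param n_perm,alpha Permutation count and stopping level for
#'   `recursive_split`.
#' @return An object of class `segmentation_params`.
#' @export
segmentation_params <- function(log2_cutoff = 0.25, min_length = 5000L,
                                max_neutral_gap_bins = 0L,
                                method = c("run_merge", "recursive_split"),
                                n_perm = 1000L, alpha = 0.01) {
  if (log2_cutoff <= 0) stopf("`log2_cutoff` must be positive")
  if (min_length < 0) stopf("`min_length` must be >= 0")
  structure(list(log2_cutoff = log2_cutoff, min_length = as.integer(min_length),
                 max_neutral_gap_bins = as.integer(max_neutral_gap_bins),
                 method = match.arg(method), n_perm = as.integer(n_perm),
                 alpha = alpha),
            class = "segmentation_params")
}

empty_segments <- function() {
  data.frame(chrom = character(0), start = integer(0), end = integer(0),
             mean_log2 = numeric(0), call = character(0),
             rt_score = numeric(0), rt_label = character(0),
             stringsAsFactors = FALSE)
}

# maximal two-sample t statistic split of x; returns list(stat, k) or NULL
best_split <- function(x) {
  n <- length(x)
  if (n < 4) return(NULL)
  cs <- cumsum(x); cs2 <- cumsum(x^2); tot <- cs[n]; tot2 <- cs2[n]
  ks <- 2:(n - 2)
  n1 <- ks; n2 <- n - ks
  s1 <- cs[ks]; s2 <- tot - s1
  ss1 <- cs2[ks] - s1^2 / n1
  ss2 <- (tot2 - cs2[ks]) - s2^2 / n2
  pooled <- (ss1 + ss2) / (n - 2)
  tstat <- abs(s1 / n1 - s2 / n2) / sqrt(pmax(pooled, 1e-12) * (1 / n1 + 1 / n2))
  k <- ks[which.max(tstat)]
  list(stat = max(tstat), k = k)
}

recursive_split_bounds <- function(x, n_perm, alpha) {
  n <- length(x)
  sp <- best_split(x)
  if (is.null(sp) || !is.finite(sp$stat)) return(c(1L, n))
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    ps <- best_split(sample(x))
    if (!is.null(ps) && ps$stat >= sp$stat) exceed <- exceed + 1L
    if (exceed > alpha * n_perm) break  # early stop: already non-significant
  }
  p <- (exceed + 1) / (n_perm + 1)
  if (p > alpha) return(c(1L, n))
  left <- recursive_split_bounds(x[1:sp$k], n_perm, alpha)
  right <- recursive_split_bounds(x[(sp$k + 1):n], n_perm, alpha)
  c(left, right + sp$k)
}

#' Segment a log2 depth-ratio track into CNV calls
#'
#' Under `run_merge`, each bin is classed gain (`>= +cutoff`), loss
#' (`<= -cutoff`) or neutral; maximal same-class runs (optionally bridging
#' short neutral gaps) become segments whose `mean_log2` is the mean over
#' member bins. Under `recursive_split`, the track is recursively split at
#' the maximal two-sample t statistic with a permutation stopping rule and
#' the resulting segment means are thresholded at the same cutoff. In both
#' cases segments no longer than `min_length` are dropped.
#'
#' @param log2ratio Per-bin log2 ratio (finite).
#' @param genome A `genome_model` matching the vector.
#' @param params A [segmentation_params()].
#' @return data.frame of segments with columns `chrom`, `start`, `end`,
#'   `mean_log2`, `call` and placeholder `rt_score`/`rt_label` columns
#'   (filled by [assign_rt()]).
#' @export
segment_track <- function(log2ratio, genome, params = segmentation_params()) {
  stopifnot(inherits(genome, "genome_model"), inherits(params, "segmentation_params"))
  if (length(log2ratio) != n_bins(genome)) stopf("log2ratio length mismatch")
  if (any(!is.finite(log2ratio))) stopf("non-finite log2 ratios")

  out <- list()
  for (ch in unique(genome$bins$chrom)) {
    sel <- which(genome$bins$chrom == ch)
    x <- log2ratio[sel]
    bins <- genome$bins[sel, , drop = FALSE]
    runs <- if (params$method == "run_merge") {
      run_merge_runs(x, params)
    } else {
      bounds <- recursive_split_bounds(x, params$n_perm, params$alpha)
      starts <- bounds[seq(1, length(bounds), by = 2)]
      ends <- bounds[seq(2, length(bounds), by = 2)]
      keep <- abs(vapply(seq_along(starts),
                         function(i) mean(x[starts[i]:ends[i]]), 0)) >= params$log2_cutoff
      data.frame(from = starts[keep], to = ends[keep])
    }
    if (nrow(runs) == 0) next
    seg <- data.frame(
      chrom = ch,
      start = bins$start[runs$from],
      end = bins$end[runs$to],
      mean_log2 = vapply(seq_len(nrow(runs)),
                         function(i) mean(x[runs$from[i]:runs$to[i]]), 0),
      stringsAsFactors = FALSE
    )
    seg$call <- ifelse(seg$mean_log2 >= params$log2_cutoff, "gain",
                       ifelse(seg$mean_log2 <= -params$log2_cutoff, "loss", NA))
    seg <- seg[!is.na(seg$call) & (seg$end - seg$start) > params$min_length, , drop = FALSE]
    out[[ch]] <- seg
  }
  if (length(out) == 0) return(empty_segments())
  res <- do.call(rbind, out)
  if (nrow(res) == 0) return(empty_segments())
  rownames(res) <- NULL
  res$rt_score <- NA_real_
  res$rt_label <- NA_character_
  res
}

# same-class run extraction with neutral-gap bridging
run_merge_runs <- function(x, params) {
  cls <- ifelse(x >= params$log2_cutoff, 1L, ifelse(x <= -params$log2_cutoff, -1L, 0L))
  r <- rle(cls)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(from = starts, to = ends, cls = r$values)
  if (params$max_neutral_gap_bins > 0 && nrow(runs) >= 3) {
    i <- 1L
    while (i <= nrow(runs) - 2L) {
      if (runs$cls[i] != 0 && runs$cls[i + 1L] == 0 &&
          runs$cls[i + 2L] == runs$cls[i] &&
          (runs$to[i + 1L] - runs$from[i + 1L] + 1L) <= params$max_neutral_gap_bins) {
        runs$to[i] <- runs$to[i + 2L]
        runs <- runs[-c(i + 1L, i + 2L), , drop = FALSE]
      } else i <- i + 1L
    }
  }
  runs[runs$cls != 0, c("from", "to"), drop = FALSE]
}

#' Annotate CNV segments with replication-timing scores
#'
#' Each segment's `rt_score` is the maximum RT value over all genome bins it
#' overlaps by at least 1 bp; `rt_label` is `"earlier"` when the score is
#' strictly positive and `"later"` otherwise (an exact 0 is labelled later
#' with a warning).
#'
#' @param segments Segment data.frame from [segment_track()].
#' @param genome A `genome_model`.
#' @param rt Per-bin RT vector (defaults to `genome$rt`).
#' @return The segments with `rt_score` and `rt_label` filled in.
#' @export
assign_rt <- function(segments, genome, rt = genome$rt) {
  stopifnot(inherits(genome, "genome_model"))
  if (length(rt) != n_bins(genome)) stopf("rt length mismatch")
  if (nrow(segments) == 0) return(segments)
  for (i in seq_len(nrow(segments))) {
    hit <- genome$bins$chrom == segments$chrom[i] &
      genome$bins$start < segments$end[i] & genome$bins$end > segments$start[i]
    if (!any(hit)) stopf("segment %s:%d-%d overlaps no bin",
                         segments$chrom[i], segments$start[i], segments$end[i])
    segments$rt_score[i] <- max(rt[hit])
  }
  if (any(segments$rt_score == 0)) warnf("segment(s) with rt_score exactly 0 labelled 'later'")
  segments$rt_label <- ifelse(segments$rt_score > 0, "earlier", "later")
  segments
}

#' Gain-in-early / loss-in-late enrichment scores
#'
#' `es_gain = (n_gain_early / n_loss_early) / (n_gain / n_loss)` and
#' `es_loss = (n_loss_late / n_gain_late) / (n_loss / n_gain)`. When any
#' cell of a ratio is zero, the pseudocount is added to all four cells of
#' that ratio (Haldane-Anscombe) and the result is flagged.
#'
#' @param segments RT-annotated segment data.frame.
#' @param pseudocount Value added to zero-containing ratios (default 0.5).
#' @return List of counts and scores (class `enrichment_result`).
#' @export
enrichment_scores <- function(segments, pseudocount = 0.5) {
  need <- c("call", "rt_label")
  if (!all(need %in% names(segments))) stopf("segments must carry call and rt_label")
  ge <- sum(segments$call == "gain" & segments$rt_label == "earlier")
  gl <- sum(segments$call == "gain" & segments$rt_label == "later")
  le <- sum(segments$call == "loss" & segments$rt_label == "earlier")
  ll <- sum(segments$call == "loss" & segments$rt_label == "later")
  n_gain <- ge + gl
  n_loss <- le + ll
  if (n_gain == 0 || n_loss == 0) stopf("ES undefined: need at least one gain and one loss")
  flag <- FALSE
  ratio4 <- function(a, b, c, d) {
    if (min(a, b, c, d) == 0) {
      flag <<- TRUE
      a <- a + pseudocount; b <- b + pseudocount
      c <- c + pseudocount; d <- d + pseudocount
    }
    (a / b) / (c / d)
  }
  es_gain <- ratio4(ge, le, n_gain, n_loss)
  es_loss <- ratio4(ll, gl, n_loss, n_gain)
  structure(list(n_gain_early = ge, n_gain_late = gl,
                 n_loss_early = le, n_loss_late = ll,
                 es_gain = es_gain, es_loss = es_loss,
                 pseudocount_used = flag),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("gains early/late %d/%d, losses early/late %d/%d; ES_gain = %.3f, ES_loss = %.3f%s\n",
              x$n_gain_early, x$n_gain_late, x$n_loss_early, x$n_loss_late,
              x$es_gain, x$es_loss,
              if (x$pseudocount_used) " (pseudocount)" else ""))
  invisible(x)
}

#' Replication-timing balance tests for CNV calls
#'
#' Within-group: two-sided binomial tests of the number of early gains
#' (and early losses) against the overall early fraction of all segments.
#' With a `reference` list, gains and losses are each compared between the
#' two lists on a 2x2 (list x early/late) table using Fisher's exact test
#' when any expected cell is below 5 and the chi-square test otherwise; the
#' single-list gain/loss x early/late association is tested the same way.
#'
#' @param segments RT-annotated segment data.frame.
#' @param reference Optional second segment data.frame to compare against.
#' @return List of tables and p-values.
#' @export
rt_balance_tests <- function(segments, reference = NULL) {
  if (nrow(segments) == 0) stopf("no segments")
  tab <- function(seg) {
    matrix(c(sum(seg$call == "gain" & seg$rt_label == "earlier"),
             sum(seg$call == "gain" & seg$rt_label == "later"),
             sum(seg$call == "loss" & seg$rt_label == "earlier"),
             sum(seg$call == "loss" & seg$rt_label == "later")),
           nrow = 2, byrow = TRUE,
           dimnames = list(c("gain", "loss"), c("earlier", "later")))
  }
  test_2x2 <- function(m) {
    if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
      stopf("degenerate 2x2 table with an all-zero margin")
    }
    expected <- outer(rowSums(m), colSums(m)) / sum(m)
    if (any(expected <= 5)) {
      list(method = "fisher", p = stats::fisher.test(m)$p.value)
    } else {
      list(method = "chisq", p = stats::chisq.test(m, correct = FALSE)$p.value)
    }
  }
  p0 <- mean(segments$rt_label == "earlier")
  t1 <- tab(segments)
  within <- list(
    gain = stats::binom.test(t1["gain", "earlier"], sum(t1["gain", ]), p = p0)$p.value,
    loss = stats::binom.test(t1["loss", "earlier"], sum(t1["loss", ]), p = p0)$p.value
  )
  res <- list(table = t1, within = within, association = test_2x2(t1))
  if (!is.null(reference)) {
    t2 <- tab(reference)
    between <- lapply(c(gain = "gain", loss = "loss"), function(cl) {
      test_2x2(rbind(segments = t1[cl, ], reference = t2[cl, ]))
    })
    res$reference_table <- t2
    res$between <- between
  }
  res
}
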
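# Shared fixtures and independent oracles, all generated in code.

# small genome used across depth/cnv tests
tiny_genome <- function(n = 8, bin_size = 10000L, rt = NULL) {
  bins <- data.frame(chrom = "chr1",
                     start = (seq_len(n) - 1L) * bin_size,
                     end = seq_len(n) * bin_size)
  if (is.null(rt)) rt <- sin(seq_len(n))
  genome_model(bins, bin_size, gc = rep(0.5, n), rt = rt)
}

# the high-SPR depth fixture: 5 kb windows so the strict >5 kb length filter
# removes isolated single-window noise calls
high_spr_fixture <- function(seed, n_bins = 5000, mean_depth = 100,
                             spikes = list(), n_cells = 200) {
  g <- make_genome(n_bins, bin_size = 5000L, n_chroms = 1L,
                   rt_amplitude = 2, gc_rt_corr = 0, seed = seed)
  tr <- simulate_wgs_bins(g, phase_composition(0.30, 0.55, 0.15),
                          n_cells = n_cells, mean_depth = mean_depth,
                          spikes = spikes, seed = seed)
  list(genome = g, track = tr)
}

# confounded two-group expression design: groups with the reported
# mESC-like (3% G1, 88% S, 9% G2M) and mNPC-like (69% G1, 17% S, 15% G2M)
# compositions; cell-cycle genes vary along the axes on which the
# compositions differ, group genes have |log2FC| = 2 and no phase effect
confounded_design <- function(seed, n_null = 600, n_cc = 150, n_grp = 150,
                              cells_per_group = 200) {
  ng <- n_null + n_cc + n_grp
  pe <- matrix(1, ng, 3)
  kinds <- list(c(1, 6, 6), c(1, 8, 2), c(8, 1, 1), c(6, 1, 6))
  lfc <- rep(0, ng)
  withr::with_seed(seed + 90000, {
    for (i in seq_len(n_cc)) pe[n_null + i, ] <- kinds[[sample(4, 1)]]
    lfc[(n_null + n_cc + 1):ng] <- sample(c(-2, 2), n_grp, replace = TRUE)
  })
  cells <- rbind(A = round(cells_per_group * c(0.03, 0.88, 0.09)),
                 B = round(cells_per_group * c(0.69, 0.17, 0.15)))
  colnames(cells) <- c("G1", "S", "G2M")
  list(
    design = expression_design(ng, cells, phase_effect = pe, group_log2fc = lfc,
                               baseline_mean = rep(5, ng), seed = seed),
    cc_genes = paste0("gene", (n_null + 1):(n_null + n_cc)),
    grp_genes = paste0("gene", (n_null + n_cc + 1):ng),
    null_genes = paste0("gene", seq_len(n_null))
  )
}

# marker-structured design for phase-assignment tests
marker_design <- function(seed, ng = 500, per_phase = 50) {
  pe <- matrix(1, ng, 3)
  pe[1:30, ] <- matrix(rep(c(8, 1, 1), each = 30), ncol = 3)
  pe[31:60, ] <- matrix(rep(c(1, 8, 1), each = 30), ncol = 3)
  pe[61:90, ] <- matrix(rep(c(1, 1, 8), each = 30), ncol = 3)
  cells <- rbind(A = c(G1 = per_phase, S = per_phase, G2M = per_phase),
                 B = c(G1 = 0, S = 0, G2M = 0))
  list(
    design = expression_design(ng, cells, phase_effect = pe, seed = seed),
    markers = marker_sets(g1 = paste0("gene", 1:30), s = paste0("gene", 31:60),
                          g2m = paste0("gene", 61:90))
  )
}

# --- independent oracles -------------------------------------------------

# exact two-sided Fisher p by hypergeometric enumeration on a 2x2 table
fisher_enum_p <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  xs <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(xs, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# O(n^2) pairwise solo oracle
solo_oracle <- function(pos, window = 100) {
  vapply(seq_along(pos), function(i) {
    all(abs(pos[-i] - pos[i]) > window)
  }, TRUE)
}

# base-pair coverage oracle for interval merge/intersection on small ranges
coverage_vector <- function(df, max_bp) {
  v <- logical(max_bp)
  for (i in seq_len(nrow(df))) {
    if (df$end[i] > df$start[i]) v[(df$start[i] + 1):df$end[i]] <- TRUE
  }
  v
}

# brute-force Benjamini-Hochberg step-up
bh_oracle <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  out <- numeric(n)
  out[o] <- pmin(adj, 1)
  out
}

# random non-degenerate interval set on [0, max_bp)
random_intervals <- function(n, max_bp, seed) {
  withr::with_seed(seed, {
    start <- sample.int(max_bp - 10L, n, replace = TRUE) - 1L
    width <- sample.int(200L, n, replace = TRUE)
    data.frame(chrom = "chr1", start = start, end = pmin(start + width, max_bp))
  })
}
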
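test_that("pseudo-mix fractions hit the target ratio with the scarce phase at 1", {
  fr <- pseudo_mix_fractions(c(G1 = 100, S = 200, G2M = 150))
  expect_equal(unname(fr["G1"]), 1)
  achieved <- fr * c(G1 = 100, S = 200, G2M = 150)
  expect_equal(unname(achieved / achieved["G1"]), c(1, 3 / 5, 2 / 5))

  fr2 <- pseudo_mix_fractions(c(G1 = 500, S = 300, G2M = 200))
  expect_equal(unname(fr2), c(1, 1, 1))   # already at 5:3:2

  fr3 <- pseudo_mix_fractions(c(G1 = 10, S = 1e6, G2M = 1e6))
  expect_equal(unname(fr3["G1"]), 1)
  expect_lt(fr3[["S"]], 1e-4)

  # the achieved ratio is exact for random totals
  for (s in 1:20) {
    set.seed(s)
    totals <- c(G1 = sample(1e3:1e6, 1), S = sample(1e3:1e6, 1), G2M = sample(1e3:1e6, 1))
    f <- pseudo_mix_fractions(totals)
    req <- f * totals
    expect_equal(unname(req / sum(req)), c(5, 3, 2) / 10, tolerance = 1e-12)
    expect_equal(max(f), 1)
  }
  expect_error(pseudo_mix_fractions(c(G1 = 0, S = 1, G2M = 1)), "positive")
})

test_that("peak merging requires a true 1 bp overlap and matches the coverage oracle", {
  p <- function(...) {
    m <- matrix(c(...), ncol = 2, byrow = TRUE)
    data.frame(chrom = "chr1", start = m[, 1], end = m[, 2])
  }
  expect_equal(nrow(merge_peaks(p(0, 100, 99, 200))), 1)
  expect_equal(nrow(merge_peaks(p(0, 100, 100, 200))), 2)   # book-ended stays split
  m3 <- merge_peaks(p(0, 50, 40, 60, 55, 70))
  expect_equal(nrow(m3), 1)
  expect_equal(c(m3$start, m3$end), c(0, 70))

  # idempotence, order invariance, and base-pair equivalence with the oracle
  for (s in 1:10) {
    iv <- random_intervals(30, 5000, seed = s)
    merged <- merge_peaks(iv)
    expect_identical(as.data.frame(merge_peaks(merged)), as.data.frame(merged))
    shuffled <- iv[sample(nrow(iv)), ]
    expect_identical(as.data.frame(merge_peaks(shuffled)), as.data.frame(merged))
    expect_identical(coverage_vector(merged, 6000), coverage_vector(iv, 6000))
  }
})

test_that("OCR set logic produces canonical cores and pseudo-mix conservation", {
  same <- peak_set(data.frame(chrom = "chr1", start = c(0, 500), end = c(100, 600)))
  res <- ocr_set_logic(list(G1 = same, S = same, G2M = same), same)
  expect_equal(as.data.frame(res$canonical), as.data.frame(same))
  expect_equal(nrow(res$phase_specific$S), 0)
  expect_equal(nrow(res$pseudo_mix_specific), 0)

  s_only <- peak_set(data.frame(chrom = "chr1", start = c(0, 900), end = c(100, 1000)))
  res2 <- ocr_set_logic(list(G1 = same, S = s_only, G2M = same), same)
  expect_true(any(res2$phase_specific$S$start == 900))

  # shifted peaks: canonical equals the brute-force base-pair intersection
  g1 <- data.frame(chrom = "chr1", start = 0, end = 100)
  s <- data.frame(chrom = "chr1", start = 99, end = 200)
  g2m <- data.frame(chrom = "chr1", start = 50, end = 150)
  res3 <- ocr_set_logic(list(G1 = peak_set(g1), S = peak_set(s), G2M = peak_set(g2m)),
                        peak_set(g1))
  cov <- coverage_vector(g1, 300) & coverage_vector(s, 300) & coverage_vector(g2m, 300)
  expect_identical(coverage_vector(as.data.frame(res3$canonical), 300), cov)

  # conservation: every pseudo-mix interval is canonical-overlapping xor specific
  for (sd in 1:5) {
    pm <- random_intervals(20, 3000, seed = sd + 100)
    sets <- lapply(1:3, function(i) peak_set(random_intervals(20, 3000, seed = sd * 7 + i)))
    names(sets) <- c("G1", "S", "G2M")
    r <- ocr_set_logic(sets, peak_set(pm))
    can_gr <- cyclegate:::gr_from_intervals(as.data.frame(r$canonical))
    pm_gr <- cyclegate:::gr_from_intervals(pm)
    overlaps <- GenomicRanges::countOverlaps(pm_gr, can_gr, minoverlap = 1L) > 0
    expect_equal(sum(!overlaps), nrow(r$pseudo_mix_specific))
  }
})

test_that("RT labelling of peaks follows the +/-0.25 rule with the max-overlap score", {
  g <- tiny_genome(3, rt = c(0.3, -0.3, 0.1))
  pk <- data.frame(chrom = "chr1", start = c(0, 10000, 20000),
                   end = c(10000, 20000, 30000))
  out <- assign_ocr_rt(pk, g)
  expect_equal(out$rt_label, c("earlier", "later", "no_change"))

  g2 <- tiny_genome(1, rt = 0.25)
  expect_warning(out2 <- assign_ocr_rt(data.frame(chrom = "chr1", start = 0, end = 10000), g2),
                 "exactly")
  expect_equal(out2$rt_label, "no_change")

  # S-specific peaks under an early bias label earlier more often than canonical
  gg <- make_genome(3000, 10000, 1, rt_amplitude = 1, seed = 71)
  ps <- simulate_peaks(gg, "S", n_shared = 400, n_specific = 600, s_early_bias = 2, seed = 9)
  pg1 <- simulate_peaks(gg, "G1", n_shared = 400, n_specific = 0, seed = 9)
  s_lab <- assign_ocr_rt(as.data.frame(ps), gg)
  c_lab <- assign_ocr_rt(as.data.frame(pg1), gg)
  p_s <- mean(s_lab$rt_label == "earlier")
  p_c <- mean(c_lab$rt_label == "earlier")
  bt <- binom.test(sum(s_lab$rt_label == "earlier"), nrow(s_lab), p = p_c)
  expect_gt(p_s, p_c)
  expect_lt(bt$p.value, 0.01)
})

test_that("the five regulatory groups partition genes exhaustively", {
  set.seed(5)
  openness <- c(runif(50, 0, 0.5), runif(50, 2, 10))
  tpm <- c(runif(50, 0, 0.5), runif(50, 2, 10))
  out <- gene_openness_expression_groups(openness, tpm)
  expect_equal(nrow(out), 100)
  expect_true(all(out$group %in% c("More_Open-Hi_Exp", "More_Open-Lo_Exp",
                                   "Less_Open-Hi_Exp", "Less_Open-Lo_Exp", "None")))
  expect_equal(sum(table(out$group)), 100)

  hi <- which(openness > quantile(openness, 0.75) & tpm > quantile(tpm, 0.75))
  expect_true(all(out$group[hi] == "More_Open-Hi_Exp"))
  mid <- which(openness >= 1 & openness <= quantile(openness, 0.75) &
                 tpm >= 1 & tpm <= quantile(tpm, 0.75))
  expect_true(all(out$group[mid] == "None"))
  expect_error(gene_openness_expression_groups(1:3, 1:3), "4 genes")
})

test_that("TPM normalisation conserves the million and orders by rate", {
  t1 <- tpm_from_counts(c(10, 10), c(1000, 1000))
  expect_equal(t1, c(5e5, 5e5))
  t2 <- tpm_from_counts(c(20, 10), c(1000, 1000))
  expect_gt(t2[1], t1[1])
  expect_lt(t2[2], t1[2])
  set.seed(3)
  t3 <- tpm_from_counts(rpois(50, 100), sample(500:5000, 50))
  expect_equal(sum(t3), 1e6, tolerance = 1e-6)
  expect_error(tpm_from_counts(c(0, 0), c(1, 1)), "all-zero")
})

test_that("OCR-CNV overlap reports sensible observed and random-control ratios", {
  g <- make_genome(1000, 10000, 1, rt_amplitude = 1, seed = 81)
  # OCRs tile 10% of the genome uniformly
  ocr <- data.frame(chrom = "chr1",
                    start = seq(0, 1e7 - 10000, by = 10000)[seq(1, 1000, by = 10)],
                    end = seq(0, 1e7 - 10000, by = 10000)[seq(1, 1000, by = 10)] + 1000)
  cnv <- data.frame(chrom = "chr1", start = c(0, 5e6), end = c(1e5, 5.1e6))
  rep_ <- ocr_cnv_overlap(ocr, list(test = cnv), g, n_random = 200, seed = 2)
  expect_lt(abs(rep_$random_mean - 0.01), 3 * rep_$random_sd / sqrt(200) + 0.01)

  whole <- data.frame(chrom = "chr1", start = 0, end = 1e7)
  rep2 <- ocr_cnv_overlap(whole, list(test = cnv), g, n_random = 10, seed = 3)
  expect_equal(rep2$observed_ratio, 1)
  expect_equal(rep2$random_mean, 1)

  rep3 <- ocr_cnv_overlap(ocr[0, ], list(test = cnv), g, n_random = 5, seed = 4)
  expect_equal(rep3$observed_ratio, 0)
})
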
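test_that("average phase profiles reflect phase-restricted expression", {
  counts <- matrix(0, 2, 6)
  counts[1, ] <- c(5, 5, 5, 5, 5, 5)
  counts[2, ] <- c(0, 0, 9, 9, 0, 0)   # expressed only in S cells
  meta <- data.frame(cell = paste0("c", 1:6),
                     phase = rep(c("G1", "S", "G2M"), each = 2),
                     group = "A", mito_fraction = 0)
  ds <- expression_dataset(counts, meta)
  prof <- average_phase_profiles(ds)
  expect_gt(prof["gene2", "S"], 0)
  expect_equal(prof["gene2", "G1"], 0)
  expect_equal(prof["gene2", "G2M"], 0)

  # two identical cells per phase: the profile equals either cell of the phase
  y_g1 <- log2(ds$counts["gene1", 1] / sum(ds$counts[, 1]) * 1e6 + 1)
  y_s <- log2(ds$counts["gene1", 3] / sum(ds$counts[, 3]) * 1e6 + 1)
  expect_equal(unname(prof["gene1", c("G1", "S")]), c(y_g1, y_s))
})

test_that("profile averaging requires two cells per phase", {
  counts <- matrix(5, 3, 5)
  meta <- data.frame(cell = paste0("c", 1:5),
                     phase = c("G1", "G1", "S", "S", "G2M"),
                     group = "A", mito_fraction = 0)
  expect_error(average_phase_profiles(expression_dataset(counts, meta)), "at least 2")
})

test_that("marker augmentation applies the correlation filter with an inclusive boundary", {
  md <- marker_design(seed = 2)
  ds <- simulate_expression(md$design)
  aug <- augment_marker_set(ds, base = md$markers, r_min = 0.1)

  # base genes preserved, conflicts resolved toward base
  expect_true(all(md$markers$g1 %in% aug$g1))
  expect_true(all(md$markers$s %in% aug$s))

  # every decision agrees with an independently recomputed correlation
  prof <- average_phase_profiles(ds)
  templates <- diag(3)
  added <- c(aug$g1, aug$s, aug$g2m)
  base_ids <- c(md$markers$g1, md$markers$s, md$markers$g2m)
  for (gname in setdiff(rownames(prof), base_ids)) {
    v <- prof[gname, ]
    r_max <- if (sd(v) == 0) -Inf else max(apply(templates, 2, function(t) cor(v, t)))
    if (r_max >= 0.1) expect_true(gname %in% added)
    else expect_true(gname %in% aug$dropped$gene)
  }

  # raising r_min never adds genes
  sets_at <- function(r) {
    a <- augment_marker_set(ds, base = md$markers, r_min = r)
    c(a$g1, a$s, a$g2m)
  }
  grid <- c(0.1, 0.3, 0.5, 0.7, 0.9)
  sets <- lapply(grid, sets_at)
  for (i in seq_len(length(grid) - 1)) {
    expect_true(all(sets[[i + 1]] %in% sets[[i]]))
  }
})

test_that("weak and flat genes are dropped with a recorded correlation", {
  # equal library sizes so the flat gene stays flat on the CPM scale
  counts <- matrix(0, 3, 6)
  counts[1, ] <- c(0, 0, 40, 40, 0, 0)     # S-restricted: r = 1 with S template
  counts[2, ] <- 5                         # flat: undefined correlation
  counts[3, ] <- c(45, 45, 5, 5, 45, 45)   # structured but below r_min = 0.999
  meta <- data.frame(cell = paste0("c", 1:6),
                     phase = rep(c("G1", "S", "G2M"), each = 2),
                     group = "A", mito_fraction = 0)
  ds <- expression_dataset(counts, meta)
  aug <- augment_marker_set(ds, base = marker_sets(), r_min = 0.999)
  expect_true("gene1" %in% aug$s)
  expect_true("gene2" %in% aug$dropped$gene)
  expect_true(is.na(aug$dropped$r[aug$dropped$gene == "gene2"]))
  expect_true("gene3" %in% aug$dropped$gene)
  expect_false(is.na(aug$dropped$r[aug$dropped$gene == "gene3"]))
})

test_that("phase assignment recovers truth on a marker-structured fixture", {
  md <- marker_design(seed = 3)
  ds <- simulate_expression(md$design)
  calls <- assign_phases(ds, md$markers)
  ev <- evaluate_phasing(calls$label, ds$cell_meta$phase)
  expect_gte(ev$macro_f1, 0.9)
  expect_true(all(calls$label == c("G1", "S", "G2M")[
    max.col(calls[, c("g1_score", "s_score", "g2m_score")], ties.method = "first")]))

  # all-zero cell: tied scores resolved to G1 with a warning
  counts <- matrix(0, 3, 4)
  counts[, 1:3] <- diag(3) * 10
  meta <- data.frame(cell = paste0("c", 1:4), phase = "G1", group = "A", mito_fraction = 0)
  ds0 <- expression_dataset(counts, meta)
  mk <- marker_sets(g1 = "gene1", s = "gene2", g2m = "gene3")
  expect_warning(c0 <- assign_phases(ds0, mk), "tied")
  expect_equal(c0$label[4], "G1")

  expect_error(assign_phases(ds0, marker_sets(g1 = "absent", s = "gene2", g2m = "gene3")),
               "no gene present")
})

test_that("evaluation metrics match hand-computed confusion arithmetic", {
  pred <- rep(c("G1", "S", "G2M"), each = 10)
  ev <- evaluate_phasing(pred, pred)
  expect_true(all(ev$per_phase$precision == 1))
  expect_true(all(ev$per_phase$sensitivity == 1))
  expect_equal(ev$macro_f1, 1)

  # per-phase TP=8 FP=2 FN=2 for every phase
  truth <- rep(c("G1", "S", "G2M"), each = 10)
  pred2 <- truth
  pred2[c(1, 2)] <- c("S", "G2M")
  pred2[c(11, 12)] <- c("G2M", "G1")
  pred2[c(21, 22)] <- c("G1", "S")
  ev2 <- evaluate_phasing(pred2, truth)
  expect_true(all(ev2$per_phase$tp == 8))
  expect_true(all(ev2$per_phase$fp == 2))
  expect_true(all(ev2$per_phase$fn == 2))
  expect_true(all(abs(ev2$per_phase$precision - 0.8) < 1e-12))
  expect_true(all(abs(ev2$per_phase$f1 - 0.8) < 1e-12))

  # constant G1 prediction on balanced truth
  ev3 <- suppressWarnings(evaluate_phasing(rep("G1", 30), truth))
  g1row <- ev3$per_phase[ev3$per_phase$phase == "G1", ]
  expect_equal(g1row$sensitivity, 1)
  expect_equal(g1row$precision, 1 / 3)
  expect_equal(ev3$per_phase$sensitivity[ev3$per_phase$phase == "S"], 0)

  # f1 lies between precision and sensitivity over random confusion matrices
  for (s in 1:30) {
    set.seed(s)
    pr <- sample(c("G1", "S", "G2M"), 60, replace = TRUE)
    tr <- sample(c("G1", "S", "G2M"), 60, replace = TRUE)
    ev4 <- suppressWarnings(evaluate_phasing(pr, tr))
    ok <- stats::complete.cases(ev4$per_phase[, c("precision", "sensitivity", "f1")])
    with(ev4$per_phase[ok, ], {
      expect_true(all(f1 >= pmin(precision, sensitivity) - 1e-12))
      expect_true(all(f1 <= pmax(precision, sensitivity) + 1e-12))
    })
  }
})

test_that("permuted labels collapse macro F1 to chance", {
  md <- marker_design(seed = 5)
  ds <- simulate_expression(md$design)
  calls <- assign_phases(ds, md$markers)
  perms <- vapply(1:50, function(s) {
    set.seed(s)
    suppressWarnings(evaluate_phasing(sample(calls$label), ds$cell_meta$phase)$macro_f1)
  }, 0)
  expect_lt(abs(mean(perms) - 1 / 3), 0.1)
})

test_that("resampled evaluation is seeded and sized correctly", {
  pred <- rep(c("G1", "S", "G2M"), each = 20)
  ev <- evaluate_phasing(pred, pred, resample_frac = 0.9, n_reps = 5, seed = 7)
  expect_length(ev$macro_f1, 5)
  expect_true(all(ev$macro_f1 == 1))
  ev2 <- evaluate_phasing(pred, pred, resample_frac = 0.9, n_reps = 5, seed = 7)
  expect_identical(ev, ev2)
})
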
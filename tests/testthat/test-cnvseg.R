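test_that("run_merge segmentation matches a hand trace and applies the length filter", {
  g <- tiny_genome(8)
  lr <- c(0, 0, 0.3, 0.3, 0, -0.3, 0, 0)
  seg <- segment_track(lr, g)
  expect_equal(nrow(seg), 2)
  expect_equal(seg$start, c(20000, 50000))
  expect_equal(seg$end, c(40000, 60000))
  expect_equal(seg$mean_log2, c(0.3, -0.3))
  expect_equal(seg$call, c("gain", "loss"))

  expect_equal(nrow(segment_track(rep(0, 8), g)), 0)

  g4 <- tiny_genome(3, bin_size = 4000L)
  expect_equal(nrow(segment_track(c(0.3, 0, 0), g4)), 0)  # 4 kb <= 5 kb dropped

  # every super-threshold bin lands in exactly one pre-filter segment
  set.seed(9)
  g2 <- tiny_genome(200, bin_size = 50000L)
  x <- rnorm(200, 0, 0.3)
  seg2 <- segment_track(x, g2, segmentation_params(min_length = 0))
  covered <- rep(0, 200)
  for (i in seq_len(nrow(seg2))) {
    idx <- which(g2$bins$start >= seg2$start[i] & g2$bins$end <= seg2$end[i])
    covered[idx] <- covered[idx] + 1
  }
  expect_true(all(covered[abs(x) >= 0.25] == 1))
  expect_true(all(covered <= 1))
})

test_that("neutral-gap bridging merges runs and recursive_split finds planted breaks", {
  g <- tiny_genome(10)
  lr <- c(0.4, 0.4, 0, 0.4, 0.4, 0, 0, 0, 0, 0)
  no_bridge <- segment_track(lr, g, segmentation_params(max_neutral_gap_bins = 0))
  bridged <- segment_track(lr, g, segmentation_params(max_neutral_gap_bins = 1))
  expect_equal(nrow(no_bridge), 2)
  expect_equal(nrow(bridged), 1)
  expect_equal(bridged$end - bridged$start, 50000)

  set.seed(4)
  g3 <- tiny_genome(120)
  x <- c(rnorm(40, 0, 0.05), rnorm(40, 0.6, 0.05), rnorm(40, 0, 0.05))
  seg <- segment_track(x, g3, segmentation_params(method = "recursive_split", n_perm = 200))
  expect_equal(nrow(seg), 1)
  expect_lt(abs(seg$start - 40 * 10000), 2 * 10000)
  expect_lt(abs(seg$end - 80 * 10000), 2 * 10000)
  expect_equal(seg$call, "gain")
})

test_that("assign_rt uses the max-overlap rule with sign labelling", {
  g <- tiny_genome(3, rt = c(-1, 0.4, -0.2))
  seg <- data.frame(chrom = "chr1", start = 0, end = 30000, mean_log2 = 0.5,
                    call = "gain", rt_score = NA_real_, rt_label = NA_character_)
  out <- assign_rt(seg, g)
  expect_equal(out$rt_score, 0.4)
  expect_equal(out$rt_label, "earlier")

  g2 <- tiny_genome(3, rt = c(-1, -0.4, -0.2))
  expect_equal(assign_rt(seg, g2)$rt_label, "later")

  g3 <- tiny_genome(3, rt = c(-1, 0, -0.2))
  expect_warning(out3 <- assign_rt(seg, g3), "exactly 0")
  expect_equal(out3$rt_label, "later")
})

test_that("enrichment scores match hand arithmetic, engage pseudocounts, and are symmetric", {
  seg <- function(call, label, k) {
    data.frame(chrom = "chr1", start = 0, end = 1, mean_log2 = 0, call = rep(call, k),
               rt_label = rep(label, k))
  }
  s1 <- rbind(seg("gain", "earlier", 9), seg("gain", "later", 1),
              seg("loss", "earlier", 1), seg("loss", "later", 9))
  es <- enrichment_scores(s1)
  expect_equal(es$es_gain, 9)
  expect_equal(es$es_loss, 9)
  expect_false(es$pseudocount_used)

  s2 <- rbind(seg("gain", "earlier", 5), seg("gain", "later", 5),
              seg("loss", "earlier", 5), seg("loss", "later", 5))
  es2 <- enrichment_scores(s2)
  expect_equal(es2$es_gain, 1)
  expect_equal(es2$es_loss, 1)

  s3 <- rbind(seg("gain", "earlier", 10), seg("loss", "later", 10))
  es3 <- enrichment_scores(s3)
  expect_true(es3$pseudocount_used)
  expect_equal(es3$es_gain, (10.5 / 0.5) / (10.5 / 10.5))

  # label-swap symmetry over random tables
  for (s in 1:20) {
    set.seed(s)
    k <- pmax(rmultinom(1, 40, rep(0.25, 4))[, 1], 1)
    tab <- rbind(seg("gain", "earlier", k[1]), seg("gain", "later", k[2]),
                 seg("loss", "earlier", k[3]), seg("loss", "later", k[4]))
    swapped <- tab
    swapped$call <- ifelse(tab$call == "gain", "loss", "gain")
    swapped$rt_label <- ifelse(tab$rt_label == "earlier", "later", "earlier")
    a <- enrichment_scores(tab); b <- enrichment_scores(swapped)
    expect_equal(a$es_gain, b$es_loss)
    expect_equal(a$es_loss, b$es_gain)
  }

  expect_error(enrichment_scores(seg("gain", "earlier", 3)), "ES undefined")
})

test_that("rt balance tests match exact references", {
  seg <- function(call, label, k) {
    data.frame(chrom = "chr1", start = 0, end = 1, call = rep(call, k), rt_label = rep(label, k))
  }
  balanced <- rbind(seg("gain", "earlier", 50), seg("gain", "later", 50),
                    seg("loss", "earlier", 50), seg("loss", "later", 50))
  res <- rt_balance_tests(balanced)
  expect_equal(res$within$gain, 1, tolerance = 1e-12)

  skew <- rbind(seg("gain", "earlier", 9), seg("gain", "later", 1),
                seg("loss", "earlier", 1), seg("loss", "later", 9))
  res2 <- rt_balance_tests(skew)
  expect_equal(res2$association$method, "fisher")
  expect_equal(res2$association$p, fisher_enum_p(9, 1, 1, 9), tolerance = 1e-9)
  expect_equal(res2$association$p, 202 / choose(20, 10), tolerance = 1e-12)

  self <- rt_balance_tests(skew, reference = skew)
  expect_equal(self$between$gain$p, 1, tolerance = 1e-9)
  expect_equal(self$between$loss$p, 1, tolerance = 1e-9)
})

test_that("pipeline: RT correction suppresses pseudo-CNVs and recovers planted spikes", {
  fx <- high_spr_fixture(seed = 51)
  lr <- depth_log2ratio(fx$track, 1)
  before <- assign_rt(segment_track(lr, fx$genome), fx$genome)
  corr <- correct_by_covariate(fx$track, fx$genome$rt, "rt", 0.01)$track
  after <- assign_rt(segment_track(depth_log2ratio(corr, 1), fx$genome), fx$genome)
  expect_gte(nrow(before), 30)
  expect_lte(nrow(after), 0.2 * nrow(before))
  expect_gte(enrichment_scores(before)$es_gain, 2)

  spikes <- list(cnv_spike("chr1", 2e6, 2e6 + 120000, 1.5),
                 cnv_spike("chr1", 9e6, 9e6 + 120000, 0.5),
                 cnv_spike("chr1", 16e6, 16e6 + 120000, 1.5))
  fs <- high_spr_fixture(seed = 52, mean_depth = 5000, spikes = spikes)
  ct <- correct_by_covariate(fs$track, fs$genome$rt, "rt", 0.01)$track
  seg <- segment_track(depth_log2ratio(ct, 1), fs$genome)
  hit_spike <- function(row) {
    any(vapply(spikes, function(sp) {
      row$start < sp$end && row$end > sp$start &&
        ((sp$copy_multiplier > 1) == (row$call == "gain"))
    }, TRUE))
  }
  hits <- vapply(seq_len(nrow(seg)), function(i) hit_spike(seg[i, ]), TRUE)
  recall <- mean(vapply(spikes, function(sp) {
    any(seg$start < sp$end & seg$end > sp$start &
          ((sp$copy_multiplier > 1) == (seg$call == "gain")))
  }, TRUE))
  expect_gte(recall, 0.9)
  expect_gte(mean(hits), 0.9)
})
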
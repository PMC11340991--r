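test_that("bins partition each chromosome with a short terminal bin", {
  gm <- toy_genome(c(chr1 = 25e6))
  b <- bin_genome(gm)
  expect_equal(b$start, c(0, 1e7, 2e7))
  expect_equal(b$end, c(1e7, 2e7, 25e6))
  gm2 <- toy_genome(c(chr1 = 5e7, chr2 = 5e7))
  b2 <- bin_genome(gm2)
  expect_equal(nrow(b2), 10)
  expect_true(all(b2$end <= gm2$chrom_lengths[b2$chrom]))
  # bin count tracks total length / width
  gmh <- make_genome_model(grch37_autosomes())
  bh <- bin_genome(gmh)
  expect_equal(nrow(bh),
               sum(ceiling(grch37_autosomes() / 1e7)))
  expect_error(bin_genome(gm, width = 0), "positive")
})

test_that("Z-scores match the hand-computed count normalization", {
  gm <- toy_genome(c(chr1 = 3e7))
  b <- bin_genome(gm)
  # counts (0, 0, 10): mean 10/3, sd 5.7735 -> Z (-0.577, -0.577, 1.155)
  sites <- data.frame(chrom = "chr1", pos = rep(2.5e7, 10))
  bt <- count_and_z(sites, b, gm)
  expect_equal(bt$count, c(0, 0, 10))
  expect_equal(bt$z, c(-0.5774, -0.5774, 1.1547), tolerance = 1e-4)
  # equal counts: all Z zero
  bt2 <- count_and_z(data.frame(chrom = "chr1", pos = c(5e6, 1.5e7, 2.5e7)),
                     b, gm)
  expect_equal(bt2$z, c(0, 0, 0))
  # no sites at all
  bt3 <- count_and_z(data.frame(chrom = character(0), pos = integer(0)),
                     b, gm)
  expect_equal(bt3$count, c(0, 0, 0))
  expect_equal(bt3$z, c(0, 0, 0))
  expect_error(count_and_z(data.frame(chrom = "chr1", pos = 4e7), b, gm),
               "outside")
})

test_that("uniform re-placement conserves totals and hits equal bins equally", {
  gm <- toy_genome(c(chr1 = 1e7, chr2 = 1e7))
  b <- bin_genome(gm)
  set.seed(71)
  null <- permute_positions(1, b, gm, n_iter = 10000)
  expect_true(all(rowSums(null) == 1))
  expect_equal(mean(null[, 1]), 0.5, tolerance = 0.04)
  # empty site set
  expect_true(all(permute_positions(0, b, gm, n_iter = 5) == 0))
  # seeded determinism
  set.seed(72); a <- permute_positions(20, b, gm, n_iter = 50)
  set.seed(72); bb <- permute_positions(20, b, gm, n_iter = 50)
  expect_identical(a, bb)
})

test_that("empirical p-values use the add-one estimator", {
  null <- matrix(c(5, 6, 7, 8), ncol = 1)
  expect_equal(empirical_pvalues(10, null), 1 / 5)   # above all draws
  expect_equal(empirical_pvalues(0, null), 1)        # below all draws
  nb <- matrix(rep(0, 999), ncol = 1)
  expect_equal(empirical_pvalues(1, nb), 1 / 1000)   # 999 iters, above all
  # tiny case against exhaustive enumeration
  nm <- matrix(c(0, 2, 3, 5,
                 1, 1, 1, 1), ncol = 2)
  obs <- c(3, 1)
  manual <- c((1 + sum(nm[, 1] >= 3)) / 5, (1 + sum(nm[, 2] >= 1)) / 5)
  expect_equal(empirical_pvalues(obs, nm), manual)
})

test_that("BH adjustment equals the brute-force step-up definition", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(c(0.005, 0.1)), c(0.01, 0.1))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  set.seed(73)
  grid <- c(0.001, 0.005, 0.01, 0.02, 0.05, 0.1, 0.25, 0.5, 0.75, 1)
  for (n in 1:12) {
    for (rep in 1:10) {
      p <- sample(grid, n, replace = TRUE)
      expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
    }
  }
  # order invariance and q >= p
  p <- runif(20)
  expect_equal(bh_adjust(p)[order(p)], bh_adjust(sort(p)))
  expect_true(all(bh_adjust(p) >= p))
})

test_that("hotspot flagging is strict at alpha", {
  bt <- data.frame(q = c(0.049, 0.05, 0.051))
  expect_equal(hotspots(bt)$hotspot, c(TRUE, FALSE, FALSE))
  expect_error(hotspots(data.frame(p = 1)), "q-values")
})

test_that("null placements are calibrated and planted enrichment is found", {
  gm <- toy_genome(c(chr1 = 1e8, chr2 = 1e8))
  b <- bin_genome(gm)
  flagged <- integer(20)
  pooled_p <- c()
  for (s in 1:20) {
    set.seed(700 + s)
    sites <- sample_numt_event(gm, n = 100)[, c("chrom", "pos")]
    bt <- numt_hotspots(sites, gm, n_iter = 1000)
    flagged[s] <- sum(bt$hotspot)
    pooled_p <- c(pooled_p, bt$p)
  }
  expect_gte(mean(flagged == 0), 0.95)
  # super-uniformity: P(p <= x) never exceeds x, so the one-sided KS
  # statistic against U(0,1) stays small (the add-one estimator is
  # discrete, which only pushes mass the conservative way)
  ks <- suppressWarnings(stats::ks.test(pooled_p, "punif",
                                        alternative = "greater"))
  expect_gt(ks$p.value, 0.01)
  # one bin with 10x enrichment over 200 sites is flagged
  set.seed(74)
  base <- sample_numt_event(gm, n = 100)[, c("chrom", "pos")]
  hot <- data.frame(chrom = "chr1",
                    pos = sample.int(1e7, 100))
  bt <- numt_hotspots(rbind(base, hot), gm, n_iter = 1000)
  expect_true(bt$hotspot[bt$chrom == "chr1" & bt$start == 0])
})

test_that("stratified runs adjust within each stratum", {
  gm <- toy_genome(c(chr1 = 5e7))
  set.seed(75)
  sites <- sample_numt_event(gm, n = 60)[, c("chrom", "pos")]
  sites$tissue <- rep(c("DLPFC", "WB"), each = 30)
  bt <- numt_hotspots(sites, gm, n_iter = 200, stratify_by = "tissue")
  expect_setequal(unique(bt$stratum), c("DLPFC", "WB"))
  expect_equal(sum(bt$stratum == "DLPFC"), 5)
  for (s in unique(bt$stratum)) {
    sub <- bt[bt$stratum == s, ]
    expect_equal(sum(sub$count), 30)
    expect_equal(bh_adjust(sub$p), sub$q)
  }
})
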
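test_that("anchors below MAPQ 10 are discarded", {
  gm <- toy_genome()
  rec <- sorted_records(rbind(anchor_records(c(1000, 1100), mapq = 9),
                              anchor_records(c(5000, 5100), mapq = 10)))
  cl <- scan_discordant(rec, gm)
  expect_equal(nrow(cl), 2)
  expect_true(all(cl$mapq >= 10))
})

test_that("empty input yields zero clusters and zero calls", {
  gm <- toy_genome()
  rec <- anchor_records(integer(0))
  cl <- scan_discordant(rec, gm)
  expect_equal(nrow(cl), 0)
  expect_equal(nrow(call_numts(cl, 30, gm)), 0)
})

test_that("unsorted input is rejected, naming the first violation", {
  gm <- toy_genome()
  rec <- anchor_records(c(5000, 1000))
  expect_error(scan_discordant(rec, gm), "record 2")
  rec2 <- rbind(anchor_records(1000, chrom = "chr1"),
                anchor_records(1000, chrom = "chr2"),
                anchor_records(2000, chrom = "chr1"))
  expect_error(scan_discordant(rec2, gm), "non-contiguous")
})

test_that("clustering equals brute-force single linkage", {
  gm <- toy_genome()
  set.seed(51)
  for (rep in 1:5) {
    pos <- sort(sample.int(20000, 30))
    rec <- anchor_records(pos)
    cl <- scan_discordant(rec, gm, caller_params(cluster_window = 400))
    oracle <- brute_single_linkage(rec$chrom, rec$pos, 400)
    expect_equal(as.integer(cl$cluster_id), oracle)
  }
  # six anchors within 400 bp on one strand form a single cluster
  rec6 <- anchor_records(seq(1000, by = 390, length.out = 6))
  cl6 <- scan_discordant(rec6, gm, caller_params(cluster_window = 400))
  expect_equal(length(unique(cl6$cluster_id)), 1)
  expect_equal(nrow(cl6), 6)
})

test_that("filter flags trigger exactly at the documented thresholds", {
  gm <- toy_genome()
  p <- caller_params()
  # support: 3 pairs -> min_support; 4 pairs -> no min_support flag
  c3 <- scan_discordant(anchor_records(c(1000, 1100, 1200)), gm, p)
  call3 <- call_numts(c3, 30, gm, p)
  expect_match(call3$filter, "min_support")
  c4 <- scan_discordant(anchor_records(c(1000, 1100, 1200, 1300)), gm, p)
  call4 <- call_numts(c4, 30, gm, p)
  expect_no_match(call4$filter, "min_support")
  # depth: 4x -> min_depth; 5x -> clean
  expect_match(call_numts(c4, 4, gm, p)$filter, "min_depth")
  expect_no_match(call_numts(c4, 5, gm, p)$filter, "min_depth")
  # quality: summed anchor MAPQ 49 -> min_qual; 52 -> clean
  cq <- scan_discordant(anchor_records(c(1000, 1100, 1200, 1300),
                                       mapq = c(12, 12, 12, 13)), gm, p)
  expect_match(call_numts(cq, 30, gm, p)$filter, "min_qual")
  cq2 <- scan_discordant(anchor_records(c(1000, 1100, 1200, 1300),
                                        mapq = 13), gm, p)
  expect_no_match(call_numts(cq2, 30, gm, p)$filter, "min_qual")
  # anchored span: union 149 bp -> anchor_lt150; 150 bp -> clean
  ca <- scan_discordant(anchor_records(c(1000, 1100, 1200, 1300),
                                       span = 38, read_length = 38), gm, p)
  sp <- call_numts(ca, 30, gm, p)
  expect_equal(sp$anchored_span, 4 * 38)
  expect_equal(anchored_span_check(
    anchor_records(c(1, 200), span = c(100, 50)))$span, 150)
  expect_true(anchored_span_check(
    anchor_records(c(1, 200), span = c(100, 50)))$pass)
  expect_false(anchored_span_check(
    anchor_records(c(1, 200), span = c(100, 49)))$pass)
  expect_equal(anchored_span_check(
    anchor_records(integer(0)))$span, 0)
  # two disjoint anchors of 100 and 120 bp -> union span 220
  expect_equal(anchored_span_check(
    anchor_records(c(1, 500), span = c(100, 120)))$span, 220)
})

test_that("one-sided clusters are flagged, paired clusters are not", {
  gm <- toy_genome()
  p <- caller_params()
  fwd <- anchor_records(c(1000, 1100, 1200, 1300), strand = "+")
  rev <- anchor_records(c(1500, 1600, 1700, 1800), strand = "-")
  both <- sorted_records(rbind(fwd, rev))
  cl <- scan_discordant(both, gm, p)
  call <- call_numts(cl, 30, gm, p)
  expect_equal(nrow(call), 1)
  expect_no_match(call$filter, "one_sided")
  expect_equal(call$support, 8)
  # breakpoint between the innermost edges: fwd 1300+151, rev 1500
  expect_gte(call$pos + call$ci_lo, 1451)
  expect_lte(call$pos + call$ci_hi, 1500)
  one <- call_numts(scan_discordant(fwd, gm, p), 30, gm, p)
  expect_match(one$filter, "one_sided")
})

test_that("compute_vaf follows the supporting/coverage definition", {
  expect_equal(compute_vaf(0, 30), 0)
  expect_equal(compute_vaf(5, 45), 5 / 45)
  expect_equal(round(compute_vaf(5, 45), 4), 0.1111)
  expect_equal(compute_vaf(60, 30), 1)  # clipped
  expect_error(compute_vaf(5, 0), "positive")
})

test_that("a planted insertion is recovered as a single PASS call", {
  gm <- toy_genome()
  set.seed(52)
  ev <- sample_numt_event(gm, numt_length_model("fixed", length = 1500))
  ev$vaf <- 0.5
  aln <- simulate_read_evidence(gm, ev, depth = 30)
  calls <- detect_numts(aln, gm)
  pass <- calls[calls$filter == "PASS", ]
  expect_equal(nrow(pass), 1)
  expect_lte(abs(pass$pos - ev$pos), 20)
  expect_gt(pass$vaf, 0.15)
})

test_that("caller output is invariant to input record permutation", {
  gm <- toy_genome()
  set.seed(53)
  ev <- sample_numt_event(gm, numt_length_model("fixed", length = 1200))
  ev$vaf <- 0.5
  rec <- alignment_records(simulate_read_evidence(gm, ev, depth = 25))
  shuffled <- rec[sample.int(nrow(rec)), ]
  resorted <- shuffled[order(match(shuffled$chrom, unique(rec$chrom)),
                             shuffled$pos), ]
  a <- call_numts(scan_discordant(rec, gm), 25, gm)
  b <- call_numts(scan_discordant(resorted, gm), 25, gm)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a[order(a$pos), ], b[order(b$pos), ])
})

test_that("lowering a threshold never removes a PASS call", {
  gm <- toy_genome()
  set.seed(54)
  ev <- sample_numt_event(gm, numt_length_model("fixed", length = 900))
  ev$vaf <- 0.35
  rec <- alignment_records(simulate_read_evidence(gm, ev, depth = 25))
  tr <- coverage_track(rec, gm)
  strict <- call_numts(scan_discordant(rec, gm), tr, gm, caller_params())
  loose <- call_numts(scan_discordant(rec, gm), tr, gm,
                      caller_params(min_support = 2, min_depth = 2,
                                    min_qual = 20, min_anchor = 50))
  pass_strict <- strict$pos[strict$filter == "PASS"]
  pass_loose <- loose$pos[loose$filter == "PASS"]
  expect_true(all(pass_strict %in% pass_loose))
})

test_that("noise-only input yields no PASS calls", {
  gm <- toy_genome()
  set.seed(55)
  pass_counts <- replicate(10, {
    ev <- sample_numt_event(gm, numt_length_model("fixed", length = 1000))
    ev$vaf <- 0
    aln <- simulate_read_evidence(gm, ev, depth = 25, chimeric_rate = 1e-4)
    calls <- detect_numts(aln, gm)
    sum(calls$filter == "PASS")
  })
  expect_gte(mean(pass_counts == 0), 0.95)
})
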
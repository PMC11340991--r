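calls_df <- function(pos, sample = "S1", chrom = "chr1") {
  data.frame(sample_id = rep_len(sample, length(pos)), chrom = chrom,
             pos = pos, stringsAsFactors = FALSE)
}

test_that("the 50 bp merge window is boundary-exact", {
  u1 <- merge_callsets(calls_df(c(1000, 1050), sample = c("S1", "S2")))
  expect_equal(nrow(u1$loci), 1)
  u2 <- merge_callsets(calls_df(c(1000, 1051), sample = c("S1", "S2")))
  expect_equal(nrow(u2$loci), 2)
})

test_that("a single call set maps loci one-to-one onto calls", {
  calls <- calls_df(c(100, 5000, 9000))
  u <- merge_callsets(calls)
  expect_equal(nrow(u$loci), 3)
  expect_equal(sort(u$loci$pos), sort(calls$pos))
})

test_that("merging equals brute-force single linkage and is order-invariant", {
  set.seed(61)
  for (rep in 1:5) {
    calls <- calls_df(sample.int(3000, 40),
                      sample = sample(c("S1", "S2", "S3"), 40, TRUE))
    u <- merge_callsets(calls, window = 50)
    oracle <- brute_single_linkage(calls$chrom, calls$pos, 50)
    expect_equal(nrow(u$loci), length(unique(oracle)))
    # same partition of calls regardless of input order
    shuf <- calls[sample.int(nrow(calls)), ]
    u2 <- merge_callsets(shuf, window = 50)
    key <- function(un) {
      m <- un$members[order(un$members$pos, un$members$sample_id), ]
      unname(split(paste(m$pos, m$sample_id), m$locus_id))
    }
    expect_setequal(vapply(key(u), paste, "", collapse = "|"),
                    vapply(key(u2), paste, "", collapse = "|"))
  }
})

test_that("merging is idempotent", {
  set.seed(62)
  calls <- calls_df(sample.int(5000, 50))
  u <- merge_callsets(calls)
  reps <- data.frame(sample_id = "S1", chrom = u$loci$chrom,
                     pos = u$loci$pos)
  u2 <- merge_callsets(reps)
  expect_equal(nrow(u2$loci), nrow(u$loci))
})

test_that("population filtering is boundary-exact and reports removals", {
  u <- merge_callsets(calls_df(c(1000, 2000)))
  refs <- data.frame(chrom = "chr1", pos = 1050)
  f1 <- filter_population(u, refs)        # 1000 is at ref - 50: removed
  expect_equal(attr(f1, "n_removed"), 1L)
  expect_equal(f1$loci$pos, 2000)
  refs2 <- data.frame(chrom = "chr1", pos = 1051)
  f2 <- filter_population(u, refs2)       # now 51 bp away: kept
  expect_equal(attr(f2, "n_removed"), 0L)
  expect_warning(f3 <- filter_population(u, NULL), "empty population")
  expect_equal(f3$loci, u$loci)
})

test_that("planted population overlap is removed exactly", {
  gm <- toy_genome()
  set.seed(63)
  des <- cohort_design(data.frame(tissue = c("A", "B"), n = c(20, 20),
                                  somatic_mean = c(3, 3)),
                       pop_ref_fraction = 0.3)
  co <- simulate_cohort(gm, des)
  u <- merge_callsets(co$calls)
  f <- filter_population(u, co$pop_ref)
  ref_keys <- paste(co$pop_ref$chrom, co$pop_ref$pos)
  planted <- sum(paste(u$loci$chrom, u$loci$pos) %in% ref_keys)
  expect_equal(attr(f, "n_removed"), planted)
  expect_equal(planted, sum(!is.na(match(
    paste(co$germline_pool$chrom, co$germline_pool$pos), ref_keys))))
})

test_that("exclusivity keeps single-group loci and drops shared ones", {
  calls <- rbind(calls_df(c(1000, 1010, 995), sample = c("D1", "D2", "D3")),
                 calls_df(5000, sample = "D1"),
                 calls_df(c(8000, 8020), sample = c("D1", "W1")))
  meta <- data.frame(sample_id = c("D1", "D2", "D3", "W1"),
                     tissue = c("DLPFC", "DLPFC", "DLPFC", "WB"))
  u <- merge_callsets(calls)
  ex <- exclusive_calls(u, meta)
  expect_setequal(ex$loci$pos, c(1000, 5000))
  expect_equal(ex$loci$group[order(ex$loci$pos)], c("DLPFC", "DLPFC"))
  # single-group cohort: exclusivity is vacuous
  meta1 <- data.frame(sample_id = c("D1", "D2", "D3", "W1"),
                      tissue = "DLPFC")
  expect_equal(nrow(exclusive_calls(u, meta1)$loci), nrow(u$loci))
  # unlabeled sample errors
  expect_error(exclusive_calls(u, meta[-1, ]), "missing from the sample")
  # stricter carrier cap
  ex2 <- exclusive_calls(u, meta, max_carriers = 1)
  expect_equal(ex2$loci$pos, 5000)
})

test_that("per-sample counts equal presence-matrix margins", {
  u <- merge_callsets(rbind(
    calls_df(c(100, 5000), sample = "S1"),
    calls_df(c(120, 9000), sample = "S2")))
  meta <- data.frame(sample_id = c("S1", "S2", "S3"),
                     tissue = c("A", "A", "B"))
  cnt <- per_sample_counts(u, meta)
  pm <- presence_matrix(u)
  expect_equal(cnt$total[match(colnames(pm), cnt$sample_id)],
               unname(colSums(pm)))
  expect_equal(cnt$total[cnt$sample_id == "S3"], 0)
  # locus at 100/120 is shared within tissue A only: still exclusive
  expect_equal(cnt$exclusive, c(2, 2, 0))
})

test_that("synthetic cohort recovers the planted exclusive structure", {
  gm <- toy_genome()
  set.seed(64)
  co <- simulate_cohort(gm, cohort_design_rosmap())
  u <- merge_callsets(co$calls)
  f <- suppressWarnings(filter_population(u, co$pop_ref))
  cnt <- per_sample_counts(f, co$samples)
  dl <- cnt$exclusive[cnt$group == "DLPFC"]
  expect_equal(mean(dl), 4.13, tolerance = 0.4 / 4.13)
  # germline pool loci recur across tissues and are dropped by exclusivity
  ex <- exclusive_calls(f, co$samples)
  pool_keys <- paste(co$germline_pool$chrom, co$germline_pool$pos)
  expect_equal(sum(paste(ex$loci$chrom, ex$loci$pos) %in% pool_keys), 0)
})

test_that("numt VCF round-trips calls and filters", {
  gm <- toy_genome()
  calls <- data.frame(
    sample_id = "S1", chrom = c("chr1", "chr2"), pos = c(1000L, 2000L),
    ci_lo = c(-10L, 0L), ci_hi = c(10L, 0L),
    mt_start = c(100L, 600L), mt_end = c(500L, 700L),
    length = c(401L, 101L), support = c(8L, 3L), depth = c(30, 4),
    qual = c(99, 40), vaf = c(0.27, 0.75), anchored_span = c(400L, 120L),
    filter = c("PASS", "min_support;min_depth"), stringsAsFactors = FALSE)
  f <- tempfile(fileext = ".vcf")
  write_numt_vcf(calls, f, gm, sample_id = "S1")
  back <- read_numt_vcf(f)
  expect_equal(back$chrom, calls$chrom)
  expect_equal(back$pos, calls$pos)
  expect_equal(back$filter, calls$filter)
  expect_equal(back$mt_start, calls$mt_start)
  expect_equal(back$support, calls$support)
  expect_equal(back$vaf, calls$vaf, tolerance = 1e-6)
})
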
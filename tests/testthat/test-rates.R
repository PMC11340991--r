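test_that("OLS fit matches closed-form normal equations", {
  # noiseless line
  f <- suppressWarnings(fit_rate(0:10, 1 + 0.1 * (0:10)))
  expect_equal(f$beta1, 0.1, tolerance = 1e-12)
  expect_equal(f$r2, 1, tolerance = 1e-12)
  # hand-computed: points (0,0), (10,1), (20,3)
  f2 <- fit_rate(c(0, 10, 20), c(0, 1, 3))
  expect_equal(f2$beta1, 0.15, tolerance = 1e-12)
  expect_equal(f2$beta0, -1 / 6, tolerance = 1e-12)
  expect_equal(f2$rate_per_10_days, 1.5, tolerance = 1e-12)
  # random small inputs against the normal equations
  set.seed(91)
  for (rep in 1:20) {
    n <- sample(3:12, 1)
    x <- rnorm(n); y <- rnorm(n)
    b1 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    b0 <- mean(y) - b1 * mean(x)
    f3 <- fit_rate(x, y)
    expect_equal(f3$beta1, b1, tolerance = 1e-10)
    expect_equal(f3$beta0, b0, tolerance = 1e-10)
    expect_true(f3$ci[1] <= f3$beta1 && f3$beta1 <= f3$ci[2])
  }
  expect_error(fit_rate(c(1, 2), c(1, 2)), "3 points")
  expect_error(fit_rate(c(1, 1, 1), c(1, 2, 3)), "zero variance")
})

test_that("median normalization divides by the group median", {
  expect_equal(normalize_by_group_median(c(5, 5, 5), c("a", "a", "a")),
               c(1, 1, 1))
  expect_equal(normalize_by_group_median(c(2, 4, 6), rep("g", 3)),
               c(0.5, 1, 1.5))
  expect_warning(
    out <- normalize_by_group_median(c(0, 0, 3), rep("g", 3)),
    "zero median")
  expect_equal(out, c(0, 0, 3))
})

test_that("slope comparison is null on identical series and equals t^2", {
  a <- data.frame(day = seq(0, 100, by = 10),
                  count = seq(0, 100, by = 10) * 0.1 +
                    c(0.1, -0.1, 0.2, -0.2, 0, 0.1, -0.1, 0.2, -0.2, 0, 0.1))
  cmp <- compare_slopes(a, a, "A", "B")
  expect_lt(cmp$F, 1e-20)
  expect_gt(cmp$p, 0.999)
  expect_error(compare_slopes(a, a, "A", "A"), "must differ")
  # interaction F equals the squared two-sample slope t statistic computed
  # from the separate fits with pooled residual variance
  set.seed(92)
  b <- data.frame(day = seq(0, 100, by = 10),
                  count = seq(0, 100, by = 10) * 0.3 + rnorm(11, 0, 0.5))
  a$count <- a$count + rnorm(11, 0, 0.5)
  cmp2 <- compare_slopes(a, b, "A", "B")
  fa <- lm(count ~ day, a); fb <- lm(count ~ day, b)
  s2 <- (sum(resid(fa)^2) + sum(resid(fb)^2)) / (nrow(a) + nrow(b) - 4)
  sxx <- function(d) sum((d$day - mean(d$day))^2)
  tstat <- (coef(fb)[["day"]] - coef(fa)[["day"]]) /
    sqrt(s2 * (1 / sxx(a) + 1 / sxx(b)))
  expect_equal(cmp2$F, tstat^2, tolerance = 1e-10)
  expect_equal(unname(cmp2$slopes),
               c(coef(fa)[["day"]], coef(fb)[["day"]]), tolerance = 1e-10)
})

test_that("slope comparison detects the control/SURF1 rate contrast", {
  gm <- toy_genome()
  des <- longitudinal_design_lifespan()
  ctrl_des <- longitudinal_design(
    des$series[des$series$treatment == "none", ])
  surf_des <- longitudinal_design(
    des$series[des$series$treatment == "SURF1", ])
  set.seed(93)
  rejections <- replicate(30, {
    ctrl <- simulate_longitudinal(gm, ctrl_des)$series
    surf <- simulate_longitudinal(gm, surf_des)$series
    cmp <- compare_slopes(ctrl, surf, "control", "SURF1")
    cmp$p < 0.05
  })
  expect_gte(mean(rejections), 0.9)
})

test_that("slope comparison holds its type-I error under equal slopes", {
  set.seed(94)
  reps <- replicate(500, {
    a <- data.frame(day = seq(0, 200, length.out = 10),
                    count = 0.1 * seq(0, 200, length.out = 10) +
                      rnorm(10, 0, 1))
    b <- data.frame(day = seq(0, 200, length.out = 10),
                    count = 0.1 * seq(0, 200, length.out = 10) +
                      rnorm(10, 0, 1))
    compare_slopes(a, b, "A", "B")$p < 0.05
  })
  expect_lte(mean(reps), 0.07)
})

test_that("fold changes round half-even to one decimal", {
  expect_equal(fold_change(4.13, 0.75), 5.5)
  expect_equal(fold_change(4.13, 1.71), 2.4)
  expect_equal(fold_change(4.13, 0.26), 15.9)
  expect_equal(fold_change(3.71, 0.79), 4.7)
  expect_equal(fold_change(3, 3), 1.0)
  expect_error(fold_change(1, 0), "positive")
})

test_that("Hedge's g matches the hand-worked small-sample formula", {
  # A = (2,4), B = (1,3): mean difference 1, pooled sd sqrt(2),
  # J = 1 - 3/(4*4 - 9) = 4/7 -> g = (4/7)/sqrt(2) = 0.404061...
  g <- hedges_g(c(2, 4), c(1, 3))
  expect_equal(g$J, 4 / 7, tolerance = 1e-12)
  expect_equal(g$g, (4 / 7) / sqrt(2), tolerance = 1e-6)
  expect_equal(hedges_g(c(1, 2, 3), c(1, 2, 3))$g, 0)
  # antisymmetry under group swap
  set.seed(95)
  a <- rnorm(10); b <- rnorm(12, 1)
  expect_equal(hedges_g(a, b)$g, -hedges_g(b, a)$g, tolerance = 1e-12)
  expect_error(hedges_g(1, c(1, 2)), "at least 2")
  expect_error(hedges_g(c(1, 1), c(1, 1)), "zero pooled")
})

test_that("cohort preset separates DLPFC from cerebellum with g near 1", {
  gm <- toy_genome()
  set.seed(96)
  des <- cohort_design_rosmap()
  des$tissues <- des$tissues[des$tissues$tissue %in%
                               c("DLPFC", "cerebellum"), ]
  des$tissues$n <- c(200, 200)
  des$germline_mean <- 0
  co <- simulate_cohort(gm, des)
  counts <- table(factor(co$calls$sample_id,
                         levels = co$samples$sample_id))
  d <- counts[co$samples$tissue == "DLPFC"]
  c2 <- counts[co$samples$tissue == "cerebellum"]
  g <- hedges_g(as.numeric(d), as.numeric(c2))
  expect_equal(g$g, 1.0, tolerance = 0.2)
})

test_that("age groups use the boundary-inclusive cuts", {
  expect_equal(as.character(assign_age_group(c(84.9, 85, 92.9, 93, 100))),
               c("<85", "85-92", "85-92", ">=93", ">=93"))
  expect_error(assign_age_group(-1), "positive")
})

test_that("age association recovers planted slopes by stratum", {
  # flat counts: slope and r2 are zero
  flat <- suppressWarnings(age_association(rep(3, 30), seq(70, 99),
                                           rep("NCI", 30)))
  expect_equal(flat$slope_per_year, 0, tolerance = 1e-12)
  expect_equal(flat$r2, 0, tolerance = 1e-12)
  # planted -0.2 per year in the NCI preset
  gm <- toy_genome()
  set.seed(97)
  slopes <- replicate(25, {
    des <- cohort_design_rosmap()
    des$tissues <- data.frame(tissue = "DLPFC", n = 120,
                              somatic_mean = 4.13)
    des$germline_mean <- 0
    des$cognitive_probs <- c(NCI = 1, MCI = 0, AD = 0)
    co <- simulate_cohort(gm, des)
    counts <- as.numeric(table(factor(co$calls$sample_id,
                                      levels = co$samples$sample_id)))
    age_association(counts, co$samples$age_death,
                    co$samples$cognitive_group)$slope_per_decade
  })
  expect_equal(mean(slopes), -2, tolerance = 0.6 / 2)
  # shuffled ages destroy the association
  set.seed(98)
  des <- cohort_design_rosmap()
  des$tissues <- data.frame(tissue = "DLPFC", n = 120, somatic_mean = 4.13)
  des$germline_mean <- 0
  des$cognitive_probs <- c(NCI = 1, MCI = 0, AD = 0)
  co <- simulate_cohort(gm, des)
  counts <- as.numeric(table(factor(co$calls$sample_id,
                                    levels = co$samples$sample_id)))
  null_slopes <- replicate(20, {
    age_association(counts, sample(co$samples$age_death),
                    co$samples$cognitive_group)$slope_per_decade
  })
  expect_lt(abs(mean(null_slopes)), 0.5)
  # small strata are skipped with a warning
  expect_warning(res <- age_association(c(1, 3, 2, 5), c(70, 80, 90, 85),
                                        c("A", "A", "A", "B")),
                 "fewer than 3")
  expect_equal(res$stratum, "A")
})
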
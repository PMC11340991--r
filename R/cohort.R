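#' Design of a synthetic multi-tissue Numt cohort
#'
#' Describes a cross-sectional cohort in which each sample carries (a) a set
#' of germline Numt polymorphisms drawn from a shared population pool and
#' (b) tissue-specific somatic events at a per-tissue mean count. Somatic
#' counts may depend linearly on age at death within each cognitive group,
#' and may be overdispersed (gamma-mixed Poisson).
#'
#' @param tissues `data.frame` with columns `tissue`, `n` (samples) and
#'   `somatic_mean` (mean tissue-specific somatic Numts per sample).
#' @param germline_mean Mean number of germline polymorphisms per sample.
#' @param germline_pool_size Number of distinct germline polymorphism loci in
#'   the population pool; each sample carries each locus independently with
#'   probability `germline_mean / germline_pool_size`, so germline loci recur
#'   across samples and tissues.
#' @param pop_ref_fraction Fraction of the germline pool that is also present
#'   in the returned population reference list (emulating published
#'   population-scale Numt catalogs).
#' @param dispersion Negative-binomial size parameter for somatic counts;
#'   `Inf` (default) gives pure Poisson counts.
#' @param age_mean,age_sd,age_range Age-at-death distribution (Gaussian,
#'   truncated to `age_range`).
#' @param cognitive_probs Named probabilities over cognitive groups
#'   (`NCI`, `MCI`, `AD`).
#' @param age_slope Named per-group slope of the somatic mean in Numts per
#'   year of age at death (applied around `age_mean`, floored at 0).
#' @param vaf Somatic VAF model (see [vaf_model()]).
#' @return An object of class `numt_cohort_design`.
#' @export
cohort_design <- function(tissues,
                          germline_mean = 7.4,
                          germline_pool_size = 60,
                          pop_ref_fraction = 0.1,
                          dispersion = Inf,
                          age_mean = 89, age_sd = 7.63,
                          age_range = c(59, 108),
                          cognitive_probs = c(NCI = 0.30, MCI = 0.27, AD = 0.43),
                          age_slope = c(NCI = 0, MCI = 0, AD = 0),
                          vaf = vaf_model("cohort")) {
  stopifnot(is.data.frame(tissues),
            all(c("tissue", "n", "somatic_mean") %in% names(tissues)))
  if (any(tissues$somatic_mean < 0) || germline_mean < 0)
    stop("rates must be non-negative")
  if (pop_ref_fraction < 0 || pop_ref_fraction > 1)
    stop("'pop_ref_fraction' must be in [0, 1]")
  structure(list(tissues = tissues, germline_mean = germline_mean,
                 germline_pool_size = germline_pool_size,
                 pop_ref_fraction = pop_ref_fraction,
                 dispersion = dispersion, age_mean = age_mean,
                 age_sd = age_sd, age_range = age_range,
                 cognitive_probs = cognitive_probs, age_slope = age_slope,
                 vaf = vaf),
            class = "numt_cohort_design")
}

#' Brain/blood cohort preset
#'
#' Preset emulating the structure of a large postmortem brain + blood cohort:
#' 466 DLPFC, 260 cerebellum, 68 PCC, 4 AC, 366 whole-blood and 23 PBMC
#' samples with tissue-specific somatic means of 4.13, 0.75, 1.71, 5.5, 3.52
#' and 0.26 respectively, a shared germline mean of 7.4 (overall per-sample
#' total ~10.4), overdispersed counts (dispersion 1.05, which yields a
#' DLPFC-vs-cerebellum standardized mean difference near 1), and an
#' age-at-death effect of -0.2 somatic Numts per year in the NCI group
#' (-2 per decade) with a weaker effect in MCI and none in AD.
#'
#' @param scale Multiplier on the per-tissue sample sizes (values < 1 produce
#'   a smaller cohort with the same structure; minimum 1 sample per tissue).
#' @param ... Overrides passed on to [cohort_design()].
#' @return A `numt_cohort_design`.
#' @export
cohort_design_rosmap <- function(scale = 1, ...) {
  tissues <- data.frame(
    tissue = c("DLPFC", "cerebellum", "PCC", "AC", "WB", "PBMC"),
    n = pmax(1L, as.integer(round(scale * c(466, 260, 68, 4, 366, 23)))),
    somatic_mean = c(4.13, 0.75, 1.71, 5.5, 3.52, 0.26))
  args <- list(tissues = tissues, dispersion = 1.05,
               age_slope = c(NCI = -0.2, MCI = -0.1, AD = 0))
  args[names(list(...))] <- list(...)
  do.call(cohort_design, args)
}

#' Simulate a multi-tissue cohort call set
#'
#' Generates per-sample Numt call sets with known ground truth: a shared
#' germline polymorphism pool plus Poisson (or gamma-mixed Poisson)
#' tissue-specific somatic events, low-frequency VAFs, and a sample sheet
#' with tissue, age at death and cognitive group. Uses the current R RNG.
#'
#' @param model A `numt_genome`.
#' @param design A [cohort_design()].
#' @param length_model Length model for planted events.
#' @return A list with elements
#'   \describe{
#'     \item{calls}{`data.frame` of per-sample calls: `sample_id`, `tissue`,
#'       `chrom`, `pos`, `mt_start`, `mt_end`, `length`, `vaf`, `origin`.}
#'     \item{samples}{sample sheet: `sample_id`, `individual_id`, `tissue`,
#'       `age_death`, `cogdx` (1 = NCI, 2-3 = MCI, 4-5 = AD), `cognitive_group`.}
#'     \item{pop_ref}{population reference list (`chrom`, `pos`, `id`): the
#'       subset of the germline pool published in population catalogs.}
#'     \item{germline_pool}{all germline pool loci with their positions.}
#'   }
#' @export
simulate_cohort <- function(model, design,
                            length_model = numt_length_model()) {
  stopifnot(inherits(model, "numt_genome"),
            inherits(design, "numt_cohort_design"))
  td <- design$tissues
  n_total <- sum(td$n)

  pool_n <- design$germline_pool_size
  pool <- sample_numt_event(model, length_model, n = pool_n,
                            origin = "germline")
  pool$locus_id <- sprintf("GL%03d", seq_len(pool_n))
  carrier_p <- min(1, design$germline_mean / pool_n)
  n_ref <- round(design$pop_ref_fraction * pool_n)
  ref_idx <- if (n_ref > 0) sample.int(pool_n, n_ref) else integer(0)
  pop_ref <- data.frame(chrom = pool$chrom[ref_idx], pos = pool$pos[ref_idx],
                        id = pool$locus_id[ref_idx])

  tissue <- rep(td$tissue, td$n)
  sample_id <- sprintf("S%04d", seq_len(n_total))
  age <- stats::rnorm(n_total, design$age_mean, design$age_sd)
  age <- pmin(pmax(age, design$age_range[1]), design$age_range[2])
  grp <- sample(names(design$cognitive_probs), n_total, replace = TRUE,
                prob = design$cognitive_probs)
  cogdx <- ifelse(grp == "NCI", 1L,
                  ifelse(grp == "MCI", sample(2:3, n_total, TRUE),
                         sample(4:5, n_total, TRUE)))
  samples <- data.frame(sample_id = sample_id, individual_id = sample_id,
                        tissue = tissue, age_death = round(age, 1),
                        cogdx = cogdx, cognitive_group = grp,
                        stringsAsFactors = FALSE)

  slope <- design$age_slope[grp]
  slope[is.na(slope)] <- 0
  base_mean <- td$somatic_mean[match(tissue, td$tissue)]
  mu <- pmax(0, base_mean + slope * (age - design$age_mean))
  n_som <- if (is.infinite(design$dispersion)) {
    stats::rpois(n_total, mu)
  } else {
    stats::rnbinom(n_total, size = design$dispersion, mu = mu)
  }

  calls <- vector("list", n_total)
  for (i in seq_len(n_total)) {
    germ <- which(stats::runif(pool_n) < carrier_p)
    parts <- list()
    if (length(germ)) {
      g <- pool[germ, c("chrom", "pos", "mt_start", "mt_end", "length",
                        "origin")]
      g$vaf <- round(pmin(pmax(stats::rnorm(length(germ), 0.5, 0.05),
                               0.05), 1), 4)
      parts$germ <- g
    }
    if (n_som[i] > 0) {
      s <- sample_numt_event(model, length_model, n = n_som[i])
      s$vaf <- round(rvaf(n_som[i], design$vaf), 4)
      parts$som <- s
    }
    if (length(parts)) {
      cs <- do.call(rbind, parts)
      cs$sample_id <- sample_id[i]
      cs$tissue <- tissue[i]
      calls[[i]] <- cs
    }
  }
  calls <- if (any(!vapply(calls, is.null, logical(1)))) {
    do.call(rbind, calls[!vapply(calls, is.null, logical(1))])
  } else {
    data.frame(chrom = character(0), pos = integer(0),
               mt_start = integer(0), mt_end = integer(0),
               length = integer(0), origin = character(0),
               vaf = numeric(0), sample_id = character(0),
               tissue = character(0))
  }
  rownames(calls) <- NULL
  calls <- calls[, c("sample_id", "tissue", "chrom", "pos", "mt_start",
                     "mt_end", "length", "vaf", "origin")]
  list(calls = calls, samples = samples, pop_ref = pop_ref,
       germline_pool = pool)
}
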
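#' Pipeline run configuration
#'
#' Bundles the analysis thresholds (all defaulting to the detection and
#' testing criteria used throughout the package), the seed, and the
#' synthetic-scenario sizes for [run_pipeline()]. Configurations
#' round-trip through YAML via [read_run_config()] / [write_run_config()].
#'
#' @param seed Integer seed recorded in every manifest and used for every
#'   source of randomness.
#' @param min_mapq,min_support,min_depth,min_qual Caller thresholds (see
#'   [caller_params()]).
#' @param merge_window Call-set merge / population-match window in bp.
#' @param bin_width Hotspot bin width in bp.
#' @param n_iter Hotspot permutation iterations.
#' @param alpha Hotspot significance level.
#' @param cohort_scale Scale factor on the cohort preset sample sizes.
#' @param read_depth Fold coverage for the read-evidence demo stage.
#' @return A list of class `numt_run_config`.
#' @export
run_config <- function(seed = 1L, min_mapq = 10, min_support = 4,
                       min_depth = 5, min_qual = 50, merge_window = 50,
                       bin_width = 1e7, n_iter = 1000, alpha = 0.05,
                       cohort_scale = 0.05, read_depth = 30) {
  cfg <- list(seed = as.integer(seed), min_mapq = min_mapq,
              min_support = min_support, min_depth = min_depth,
              min_qual = min_qual, merge_window = merge_window,
              bin_width = bin_width, n_iter = n_iter, alpha = alpha,
              cohort_scale = cohort_scale, read_depth = read_depth)
  if (any(unlist(cfg[-1]) <= 0)) stop("thresholds must be positive")
  structure(cfg, class = "numt_run_config")
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname run_config
#' @param config A `numt_run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Run the Numt analysis pipeline on a synthetic scenario
#'
#' Orchestrates the stages end to end on seeded synthetic data:
#' `simulate` (genome, cohort call sets, longitudinal series, read
#' evidence), `call` (insertion calling on the simulated reads), `merge`
#' (unified cohort loci), `somatic` (population filtering + tissue-exclusive
#' extraction), `hotspot`, `annotate` (genic content), `rates`
#' (accumulation slopes and comparisons), and `mtdnacn`. Each stage writes
#' its outputs under `out_dir` and the run ends with a JSON manifest of
#' parameters and file checksums; rerunning with the same configuration
#' reproduces identical checksums.
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Ordered subset of stages to run; later stages require the
#'   artifacts of earlier ones.
#' @return The manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = run_config(), out_dir = "numt-run",
                         stages = c("simulate", "call", "merge", "somatic",
                                    "hotspot", "annotate", "rates",
                                    "mtdnacn")) {
  stopifnot(inherits(config, "numt_run_config"))
  all_stages <- c("simulate", "call", "merge", "somatic", "hotspot",
                  "annotate", "rates", "mtdnacn")
  stages <- match.arg(stages, all_stages, several.ok = TRUE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  state_path <- file.path(out_dir, "state.rds")
  st <- if (file.exists(state_path)) readRDS(state_path) else list()
  outputs <- character(0)
  pth <- function(f) file.path(out_dir, f)

  for (stage in all_stages) {
    if (!stage %in% stages) next
    set.seed(config$seed + match(stage, all_stages))
    message("[", stage, "]")
    if (stage == "simulate") {
      st$model <- make_genome_model(
        c(chr1 = 30e6, chr2 = 25e6, chr3 = 20e6, chr4 = 15e6),
        annotation = simulate_annotation(
          c(chr1 = 30e6, chr2 = 25e6, chr3 = 20e6, chr4 = 15e6)))
      st$cohort <- simulate_cohort(st$model,
                                   cohort_design_rosmap(config$cohort_scale))
      st$longi <- simulate_longitudinal(st$model,
                                        longitudinal_design_lifespan())
      ev <- sample_numt_event(st$model,
                             numt_length_model("fixed", length = 1500))
      ev$vaf <- 0.4
      st$truth_event <- ev
      aln <- simulate_read_evidence(st$model, ev, depth = config$read_depth)
      write_sam(aln, pth("evidence.sam"), st$model)
      utils::write.table(st$cohort$samples, pth("samples.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      utils::write.table(st$cohort$calls, pth("cohort_calls.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(st$longi$series, pth("longitudinal.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(st$cohort$pop_ref, pth("pop_ref.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "evidence.sam", "samples.tsv",
                   "cohort_calls.tsv", "longitudinal.tsv", "pop_ref.tsv")
    } else if (stage == "call") {
      .need(st, "model", "call")
      pars <- caller_params(min_mapq = config$min_mapq,
                            min_support = config$min_support,
                            min_depth = config$min_depth,
                            min_qual = config$min_qual)
      st$calls <- detect_numts(pth("evidence.sam"), st$model, pars,
                               sample_id = "demo")
      write_numt_vcf(st$calls, pth("calls.vcf"), st$model, "demo")
      outputs <- c(outputs, "calls.vcf")
    } else if (stage == "merge") {
      .need(st, "cohort", "merge")
      st$unified <- merge_callsets(st$cohort$calls,
                                   window = config$merge_window)
      utils::write.table(st$unified$loci, pth("merged_loci.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "merged_loci.tsv")
    } else if (stage == "somatic") {
      .need(st, "unified", "somatic")
      flt <- filter_population(st$unified, st$cohort$pop_ref,
                               window = config$merge_window)
      st$somatic <- exclusive_calls(flt, st$cohort$samples)
      counts <- per_sample_counts(flt, st$cohort$samples)
      utils::write.table(st$somatic$loci, pth("somatic_loci.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      utils::write.table(counts, pth("per_sample_counts.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "somatic_loci.tsv", "per_sample_counts.tsv")
    } else if (stage == "hotspot") {
      .need(st, "somatic", "hotspot")
      bt <- numt_hotspots(
        data.frame(chrom = st$somatic$loci$chrom,
                   pos = st$somatic$loci$pos),
        st$model, width = config$bin_width, n_iter = config$n_iter,
        alpha = config$alpha)
      utils::write.table(bt, pth("hotspots.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "hotspots.tsv")
    } else if (stage == "annotate") {
      .need(st, "somatic", "annotate")
      cats <- classify_site(st$somatic$loci, st$model)
      tally <- enrichment_test(cats, st$model)
      utils::write.table(tally, pth("genic_content.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      outputs <- c(outputs, "genic_content.tsv")
    } else if (stage == "rates") {
      .need(st, "longi", "rates")
      ser <- st$longi$series
      ser$arm <- ifelse(ser$treatment == "none", "control", ser$treatment)
      fits <- do.call(rbind, lapply(split(ser, ser$arm), function(s) {
        f <- fit_rate(s$day, s$count)
        data.frame(arm = s$arm[1], slope_per_day = f$beta1,
                   rate_per_10_days = f$rate_per_10_days,
                   ci_lo = 10 * f$ci[1], ci_hi = 10 * f$ci[2],
                   r2 = f$r2, p = f$p, n = f$n)
      }))
      ctrl <- ser[ser$arm == "control", ]
      ctrl$norm <- normalize_by_group_median(ctrl$count, ctrl$arm)
      surf <- ser[ser$arm == "SURF1", ]
      surf$norm <- normalize_by_group_median(surf$count, surf$arm)
      cmp <- compare_slopes(
        data.frame(day = ctrl$day, count = ctrl$norm),
        data.frame(day = surf$day, count = surf$norm),
        "control", "SURF1")
      fits$fold_vs_control <- vapply(fits$rate_per_10_days, fold_change,
                                     numeric(1),
                                     b = fits$rate_per_10_days[
                                       fits$arm == "control"])
      st$rates <- list(fits = fits, comparison = cmp)
      utils::write.table(fits, pth("rates.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, "rates.tsv")
    } else if (stage == "mtdnacn") {
      .need(st, "model", "mtdnacn")
      small <- make_genome_model(c(chr1 = 2e5, chr2 = 2e5))
      cn <- vapply(c(DLPFC = 4047, cerebellum = 999, WB = 172),
                   function(copies) {
        tr <- simulate_mtdna_coverage(small, depth = config$read_depth,
                                      copies_per_cell = copies)
        compute_mtdnacn(coverage_summary(tr, small))
      }, numeric(1))
      res <- data.frame(tissue = names(cn), mtdnacn = as.numeric(cn))
      res$standardized <- standardize_mtdnacn(res$mtdnacn,
                                              rep("batch1", nrow(res)))
      utils::write.table(res, pth("mtdnacn.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs <- c(outputs, "mtdnacn.tsv")
    }
  }
  saveRDS(st, state_path)
  manifest <- list(
    package = "numtogenesis",
    version = as.character(utils::packageVersion("numtogenesis")),
    seed = config$seed,
    parameters = unclass(config),
    stages = stages,
    outputs = lapply(stats::setNames(outputs, outputs), function(f)
      list(path = f, md5 = unname(tools::md5sum(pth(f))))))
  jsonlite::write_json(manifest, pth("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

.need <- function(st, what, stage) {
  if (is.null(st[[what]]))
    stop("stage '", stage, "' requires the 'simulate'",
         if (what %in% c("unified", "somatic")) " and upstream",
         " stage artifacts; run earlier stages first")
}
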
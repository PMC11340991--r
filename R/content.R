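#' Classify insertion sites by genic context
#'
#' Deterministic category lookup against the model's resolved annotation
#' tiling. Overlaps between transcripts were already resolved with the
#' precedence CDS > UTR > intron > intergenic when the model was built, so
#' every nuclear base has exactly one category.
#'
#' @param sites `data.frame(chrom, pos)` (1-based), or vectors via `pos`.
#' @param model A `numt_genome` with an annotation.
#' @return Character vector of categories, one per site.
#' @export
classify_site <- function(sites, model) {
  stopifnot(inherits(model, "numt_genome"))
  if (is.null(model$annotation))
    stop("the genome model carries no annotation")
  lens <- model$chrom_lengths[sites$chrom]
  if (anyNA(lens) || any(sites$pos < 1) || any(sites$pos > lens))
    stop("site outside the nuclear genome")
  gr <- GenomicRanges::GRanges(sites$chrom,
                               IRanges::IRanges(sites$pos, width = 1L))
  hit <- GenomicRanges::findOverlaps(gr, model$annotation, select = "first")
  model$annotation$category[hit]
}

#' Expected genome-wide category fractions
#'
#' Base-pair fraction of the nuclear genome in each category — the expected
#' distribution of insertion sites under uniform placement.
#'
#' @param model A `numt_genome` with an annotation.
#' @return Named fractions over `CDS`, `UTR`, `intron`, `intergenic`,
#'   summing to 1.
#' @export
expected_fractions <- function(model) {
  if (is.null(model$annotation))
    stop("the genome model carries no annotation")
  category_fractions(model)
}

#' Test observed genic-category proportions against genome expectation
#'
#' For each category, compares the proportion of insertion sites inside the
#' category against the rest of the genome as a 2x2 table of observed versus
#' expected counts (expected = genome base-pair fraction times the total
#' site count). Uses Pearson's chi-square test without continuity
#' correction, switching to Fisher's exact test when any expected cell of
#' the 2x2 table is below 5 (small samples).
#'
#' @param observed Named vector of observed site counts per category, or a
#'   character vector of per-site categories (from [classify_site()]).
#' @param model A `numt_genome` with annotation (supplies the expected
#'   fractions), or a named numeric vector of expected fractions.
#' @return `data.frame(category, observed, expected_fraction,
#'   expected_count, test, statistic, p)`.
#' @export
enrichment_test <- function(observed, model) {
  fr <- if (inherits(model, "numt_genome")) expected_fractions(model)
        else model
  if (is.character(observed)) {
    observed <- table(factor(observed, levels = names(fr)))
    observed <- stats::setNames(as.integer(observed), names(fr))
  }
  total <- sum(observed)
  if (total <= 0) stop("no observed sites to test")
  cats <- names(fr)
  obs <- stats::setNames(rep(0, length(cats)), cats)
  obs[names(observed)] <- observed
  rows <- lapply(cats, function(cat) {
    tab <- rbind(observed = c(obs[[cat]], total - obs[[cat]]),
                 expected = c(fr[[cat]] * total, (1 - fr[[cat]]) * total))
    expected_cells <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected_cells < 5)) {
      ft <- stats::fisher.test(round(tab))
      data.frame(category = cat, observed = obs[[cat]],
                 expected_fraction = fr[[cat]],
                 expected_count = fr[[cat]] * total,
                 test = "fisher", statistic = unname(ft$estimate),
                 p = ft$p.value, stringsAsFactors = FALSE)
    } else {
      ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
      data.frame(category = cat, observed = obs[[cat]],
                 expected_fraction = fr[[cat]],
                 expected_count = fr[[cat]] * total,
                 test = "chisq", statistic = unname(ct$statistic),
                 p = ct$p.value, stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
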
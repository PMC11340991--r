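#' Median coverage summary for mtDNA copy-number estimation
#'
#' Median per-base coverage of the mitochondrial contig and of the nuclear
#' autosomes. Reads with MAPQ = 0 (ambiguous placement) are excluded before
#' pile-up when alignment records are supplied, and masked nuclear positions
#' are excluded from the autosomal median.
#'
#' @param x Either alignment records ([read_sam()] / [alignment_records()])
#'   or a [coverage_track()] list (already filtered as desired).
#' @param model A `numt_genome` (supplies contig names, lengths and mask).
#' @return List of class `coverage_summary` with `cov_mt` and
#'   `cov_autosomal`.
#' @export
coverage_summary <- function(x, model) {
  stopifnot(inherits(model, "numt_genome"))
  track <- if (is.list(x) && !is.data.frame(x)) x
           else coverage_track(x, model, min_mapq = 1)
  if (is.null(track[[model$mt_name]]))
    stop("no mtDNA contig ('", model$mt_name, "') in the coverage input")
  cov_mt <- stats::median(as.numeric(track[[model$mt_name]]))
  vals <- lapply(names(model$chrom_lengths), function(ch) {
    cov <- track[[ch]]
    if (is.null(cov)) stop("no coverage for chromosome ", ch)
    keep <- IRanges::IRanges(1L, length(cov))
    if (!is.null(model$mask)) {
      mk <- model$mask[GenomicRanges::seqnames(model$mask) == ch]
      if (length(mk))
        keep <- IRanges::setdiff(keep, IRanges::ranges(mk))
    }
    if (!length(keep)) return(numeric(0))
    as.numeric(unlist(IRanges::Views(cov, keep), use.names = FALSE))
  })
  structure(list(cov_mt = cov_mt,
                 cov_autosomal = stats::median(unlist(vals))),
            class = "coverage_summary")
}

#' @export
print.coverage_summary <- function(x, ...) {
  cat(sprintf("coverage_summary: mtDNA %.1fx, autosomal %.1fx\n",
              x$cov_mt, x$cov_autosomal))
  invisible(x)
}

#' mtDNA copy number per cell
#'
#' `mtDNAcn = (cov_MT / cov_autosomal) * 2`: the mitochondrial-to-autosomal
#' median coverage ratio scaled by the diploid autosomal copy number.
#'
#' @param cov A [coverage_summary()], or the mtDNA coverage when
#'   `cov_autosomal` is given separately.
#' @param cov_autosomal Autosomal coverage (when `cov` is numeric).
#' @return Estimated mtDNA copies per cell.
#' @examples
#' compute_mtdnacn(3000, 30) # 200
#' @export
compute_mtdnacn <- function(cov, cov_autosomal = NULL) {
  if (inherits(cov, "coverage_summary")) {
    cov_mt <- cov$cov_mt
    cov_autosomal <- cov$cov_autosomal
  } else {
    cov_mt <- cov
  }
  if (is.null(cov_autosomal) || any(cov_autosomal <= 0))
    stop("autosomal coverage must be positive")
  2 * cov_mt / cov_autosomal
}

#' Batch-standardize mtDNA copy-number values
#'
#' Removes batch effects (brain region x DNA extraction kit) by combining a
#' log transform with within-batch z-standardization. The default order
#' applies `log10` first and then standardizes within batch (a z-score is
#' signed, so logarithmizing it directly is undefined); `order = "z_first"`
#' keeps the literal z-then-log order by shifting each batch's z-scores
#' above zero (minimum + 1) before the log.
#'
#' @param values Positive mtDNAcn values.
#' @param batch Batch labels, one per value (each batch needs >= 2 values).
#' @param order `"log_first"` (default) or `"z_first"`.
#' @return Numeric vector of transformed values with attribute
#'   `"batch_stats"` (`data.frame` of per-batch means and s.d. on the scale
#'   that was standardized).
#' @export
standardize_mtdnacn <- function(values, batch,
                                order = c("log_first", "z_first")) {
  order <- match.arg(order)
  stopifnot(length(values) == length(batch))
  if (order == "log_first" && any(values <= 0))
    stop("mtDNAcn values must be positive for the log transform")
  n <- table(batch)
  if (any(n < 2)) stop("each batch needs at least 2 values")
  out <- numeric(length(values))
  stats_rows <- list()
  for (b in names(n)) {
    i <- batch == b
    if (order == "log_first") {
      x <- log10(values[i])
      m <- mean(x); s <- stats::sd(x)
      if (s == 0) stop("zero variance in batch '", b, "'")
      out[i] <- (x - m) / s
    } else {
      m <- mean(values[i]); s <- stats::sd(values[i])
      if (s == 0) stop("zero variance in batch '", b, "'")
      z <- (values[i] - m) / s
      out[i] <- log10(z - min(z) + 1)
    }
    stats_rows[[b]] <- data.frame(batch = b, mean = m, sd = s)
  }
  attr(out, "batch_stats") <- do.call(rbind, stats_rows)
  out
}

#' Simulate a coverage track with a planted mtDNA copy number
#'
#' Per-base Poisson coverage around `depth` on the nuclear chromosomes and
#' around `depth * copies_per_cell / 2` on the mitochondrial contig — the
#' coverage structure implied by a cell carrying `copies_per_cell` mtDNA
#' copies against a diploid nuclear genome. Uses the current R RNG.
#'
#' @param model A `numt_genome`.
#' @param depth Mean autosomal fold coverage.
#' @param copies_per_cell Planted mtDNA copy number.
#' @return A coverage track ([coverage_track()] layout).
#' @export
simulate_mtdna_coverage <- function(model, depth, copies_per_cell) {
  stopifnot(inherits(model, "numt_genome"))
  out <- lapply(model$chrom_lengths, function(len)
    S4Vectors::Rle(stats::rpois(len, depth)))
  out[[model$mt_name]] <-
    S4Vectors::Rle(stats::rpois(model$mt_length,
                                depth * copies_per_cell / 2))
  out
}
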
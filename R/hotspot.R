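#' Partition the nuclear genome into fixed-width bins
#'
#' Consecutive non-overlapping bins of nominal width `width` per chromosome
#' (default 10 Mb); the terminal bin of each chromosome may be shorter. Bins
#' never span a chromosome boundary. Coordinates are 0-based half-open
#' (BED convention).
#'
#' @param model A `numt_genome`.
#' @param width Bin width in bp.
#' @return `data.frame(bin_id, chrom, start, end)`.
#' @export
bin_genome <- function(model, width = 1e7) {
  stopifnot(inherits(model, "numt_genome"))
  if (width <= 0) stop("'width' must be positive")
  out <- lapply(names(model$chrom_lengths), function(ch) {
    len <- model$chrom_lengths[[ch]]
    starts <- seq(0, len - 1, by = width)
    data.frame(chrom = ch, start = starts,
               end = pmin(starts + width, len), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- cbind(bin_id = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  out
}

#' Count insertion sites per bin and normalize to Z-scores
#'
#' The Z-score of a bin measures the deviation of its site count from the
#' genome-wide average count across all bins, in units of the across-bin
#' standard deviation; if all bins have equal counts the Z-scores are 0.
#'
#' @param sites `data.frame` with `chrom` and `pos` (1-based).
#' @param bins Output of [bin_genome()].
#' @param model A `numt_genome` (bounds checking).
#' @return `bins` with added `count` and `z` columns.
#' @export
count_and_z <- function(sites, bins, model) {
  counts <- .bin_counts(sites, bins, model)
  z <- if (length(counts) > 1 && stats::sd(counts) > 0) {
    (counts - mean(counts)) / stats::sd(counts)
  } else {
    rep(0, length(counts))
  }
  cbind(bins, count = counts, z = z)
}

.bin_counts <- function(sites, bins, model) {
  if (!nrow(sites)) return(integer(nrow(bins)))
  lens <- model$chrom_lengths[sites$chrom]
  if (anyNA(lens) || any(sites$pos < 1) || any(sites$pos > lens))
    stop("site outside the nuclear genome")
  idx <- .site_bin_index(sites$chrom, sites$pos, bins, model)
  tabulate(idx, nbins = nrow(bins))
}

# bin index of 1-based sites; bins are 0-based half-open per chromosome
.site_bin_index <- function(chrom, pos, bins, model) {
  g <- .pos_to_global(model, chrom, pos)
  gstart <- .pos_to_global(model, bins$chrom, bins$start + 1L)
  findInterval(g, gstart)
}

#' Null distribution of bin counts by uniform re-placement
#'
#' Each iteration re-places every observed site uniformly over the
#' concatenated nuclear genome and records the per-bin counts, conserving
#' the total site count per iteration. Uses the current R RNG.
#'
#' @param sites Observed sites (`chrom`, `pos`), or a single integer count.
#' @param bins Output of [bin_genome()].
#' @param model A `numt_genome`.
#' @param n_iter Number of shuffles (50,000 in the full analysis).
#' @param respect_mask If `TRUE`, re-draw placements that fall inside the
#'   model's ambiguity mask (default `FALSE`: shuffling ignores the mask).
#' @param chunk Iterations drawn per memory chunk.
#' @return Integer matrix `n_iter` x `nrow(bins)`.
#' @export
permute_positions <- function(sites, bins, model, n_iter = 50000,
                              respect_mask = FALSE, chunk = 2000L) {
  stopifnot(inherits(model, "numt_genome"), n_iter >= 1)
  n_sites <- if (is.data.frame(sites)) nrow(sites) else as.integer(sites)
  nb <- nrow(bins)
  out <- matrix(0L, n_iter, nb)
  if (n_sites == 0L) return(out)
  gstart <- .pos_to_global(model, bins$chrom, bins$start + 1L)
  total <- nuclear_size(model)
  mask_global <- NULL
  if (respect_mask && !is.null(model$mask)) {
    mk <- model$mask
    mask_global <- IRanges::IRanges(
      .pos_to_global(model, as.character(GenomicRanges::seqnames(mk)),
                     GenomicRanges::start(mk)),
      .pos_to_global(model, as.character(GenomicRanges::seqnames(mk)),
                     GenomicRanges::end(mk)))
  }
  done <- 0L
  while (done < n_iter) {
    m <- min(chunk, n_iter - done)
    g <- ceiling(stats::runif(m * n_sites) * total)
    if (!is.null(mask_global)) {
      repeat {
        inside <- IRanges::overlapsAny(
          IRanges::IRanges(g, width = 1L), mask_global)
        if (!any(inside)) break
        g[inside] <- ceiling(stats::runif(sum(inside)) * total)
      }
    }
    idx <- findInterval(g, gstart)
    iter <- rep(seq_len(m), each = n_sites)
    cnt <- tabulate(idx + (iter - 1L) * nb, nbins = nb * m)
    out[done + seq_len(m), ] <- matrix(cnt, m, nb, byrow = TRUE)
    done <- done + m
  }
  out
}

#' Empirical enrichment p-values from a permutation null
#'
#' One-sided add-one estimator:
#' `p_b = (1 + #[null count >= observed_b]) / (n_iter + 1)`, so p is never
#' exactly zero.
#'
#' @param observed Observed per-bin counts (e.g., the `count` column of
#'   [count_and_z()]).
#' @param null_matrix Matrix from [permute_positions()] with one column per
#'   bin.
#' @return Numeric vector of p-values, one per bin.
#' @export
empirical_pvalues <- function(observed, null_matrix) {
  if (length(observed) != ncol(null_matrix))
    stop("null matrix columns must align with bins")
  n_iter <- nrow(null_matrix)
  ge <- colSums(null_matrix >= matrix(observed, n_iter, length(observed),
                                      byrow = TRUE))
  (1 + ge) / (n_iter + 1)
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-invariant.
#'
#' @param pvals Numeric p-values in `[0, 1]`.
#' @return q-values of the same length.
#' @export
bh_adjust <- function(pvals) {
  if (any(is.na(pvals)) || any(pvals < 0 | pvals > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvals, method = "BH")
}

#' Flag significant hotspot bins
#'
#' A bin is a hotspot when its BH-adjusted q-value is strictly below
#' `alpha`.
#'
#' @param bin_table `data.frame` with a `q` column ([numt_hotspots()]).
#' @param alpha Significance level (default 0.05).
#' @return `bin_table` with a logical `hotspot` column.
#' @export
hotspots <- function(bin_table, alpha = 0.05) {
  if (is.null(bin_table$q)) stop("'bin_table' must carry q-values")
  bin_table$hotspot <- bin_table$q < alpha
  bin_table
}

#' Permutation hotspot test over genomic bins
#'
#' Full pipeline: bin the genome, count observed sites and Z-scores, build
#' the uniform-placement null, compute empirical p-values, BH-adjust, and
#' flag hotspots. With `stratify_by`, the test (including BH adjustment) is
#' run separately within each stratum of the sites.
#'
#' @param sites `data.frame(chrom, pos)`, optionally with the stratification
#'   column.
#' @param model A `numt_genome`.
#' @param width Bin width in bp.
#' @param n_iter Number of shuffles.
#' @param alpha Hotspot significance level on q.
#' @param stratify_by Optional column of `sites` to stratify on (e.g.
#'   tissue, cognitive group, age group).
#' @param respect_mask Passed to [permute_positions()].
#' @return A bin table (`bin_id`, `chrom`, `start`, `end`, `count`, `z`,
#'   `p`, `q`, `hotspot`); with stratification, one table per stratum bound
#'   together with a `stratum` column.
#' @export
numt_hotspots <- function(sites, model, width = 1e7, n_iter = 50000,
                          alpha = 0.05, stratify_by = NULL,
                          respect_mask = FALSE) {
  if (!is.null(stratify_by)) {
    strata <- split(sites, sites[[stratify_by]])
    out <- lapply(names(strata), function(s) {
      cbind(stratum = s,
            numt_hotspots(strata[[s]], model, width, n_iter, alpha,
                          respect_mask = respect_mask))
    })
    return(do.call(rbind, out))
  }
  bins <- bin_genome(model, width)
  bt <- count_and_z(sites, bins, model)
  null <- permute_positions(sites, bins, model, n_iter = n_iter,
                            respect_mask = respect_mask)
  bt$p <- empirical_pvalues(bt$count, null)
  bt$q <- bh_adjust(bt$p)
  hotspots(bt, alpha = alpha)
}
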
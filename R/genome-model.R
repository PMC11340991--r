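#' Build a genome model for Numt analysis
#'
#' A genome model bundles the nuclear chromosome lengths, the (circular)
#' mitochondrial genome length, an optional gene annotation, and an optional
#' ambiguity mask. It is the reference frame for event placement, binning,
#' genic classification, and coverage summaries.
#'
#' The annotation is supplied as raw gene features (categories `CDS`, `UTR`,
#' `intron`; possibly overlapping across transcripts) and is resolved to a
#' disjoint tiling of each chromosome using the precedence
#' CDS > UTR > intron > intergenic: any base covered by a CDS feature is CDS,
#' a non-CDS base covered by a UTR feature is UTR, and so on; bases covered by
#' no feature are intergenic.
#'
#' @param chrom_lengths Named numeric vector of nuclear chromosome lengths in
#'   bp. All lengths must be positive.
#' @param mt_length Length in bp of the circular mitochondrial genome
#'   (default 16569, the length of the human rCRS).
#' @param annotation Optional `data.frame` with columns `chrom`, `start`,
#'   `end` (1-based, closed) and `category` (one of `"CDS"`, `"UTR"`,
#'   `"intron"`). Intervals of the same category on the same chromosome must
#'   not overlap.
#' @param mask Optional `data.frame` with columns `chrom`, `start`, `end`
#'   (1-based, closed): ambiguous regions excluded from coverage medians.
#' @param mt_name Name of the mitochondrial contig (default `"chrM"`). Must
#'   not collide with a nuclear chromosome name.
#'
#' @return An object of class `numt_genome`: a list with elements
#'   `chrom_lengths`, `mt_length`, `mt_name`, `annotation` (a [GenomicRanges::GRanges]
#'   tiling with a `category` column, or `NULL`) and `mask` (a `GRanges` or `NULL`).
#' @examples
#' gm <- make_genome_model(c(chr1 = 5e7, chr2 = 5e7))
#' nuclear_size(gm)
#' @export
make_genome_model <- function(chrom_lengths, mt_length = 16569,
                              annotation = NULL, mask = NULL,
                              mt_name = "chrM") {
  if (length(chrom_lengths) < 1L)
    stop("at least one nuclear chromosome is required")
  if (is.null(names(chrom_lengths)) || anyDuplicated(names(chrom_lengths)) ||
      any(!nzchar(names(chrom_lengths))))
    stop("'chrom_lengths' must have unique non-empty names")
  if (any(!is.finite(chrom_lengths)) || any(chrom_lengths <= 0))
    stop("all chromosome lengths must be positive")
  if (!is.finite(mt_length) || mt_length <= 0)
    stop("'mt_length' must be positive")
  if (mt_name %in% names(chrom_lengths))
    stop("'mt_name' collides with a nuclear chromosome name")
  chrom_lengths <- round(chrom_lengths)

  model <- structure(
    list(chrom_lengths = chrom_lengths, mt_length = round(mt_length),
         mt_name = mt_name, annotation = NULL, mask = NULL),
    class = "numt_genome")

  if (!is.null(annotation))
    model$annotation <- .resolve_annotation(annotation, chrom_lengths)
  if (!is.null(mask)) {
    mk <- .as_granges(mask, chrom_lengths)
    bad <- GenomicRanges::end(mk) >
      chrom_lengths[as.character(GenomicRanges::seqnames(mk))]
    if (any(bad) || any(GenomicRanges::start(mk) < 1L))
      stop("mask intervals must lie within the genome")
    model$mask <- GenomicRanges::reduce(mk)
  }
  model
}

.as_granges <- function(df, chrom_lengths) {
  stopifnot(all(c("chrom", "start", "end") %in% names(df)))
  unknown <- setdiff(unique(df$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("unknown chromosome(s) in intervals: ", paste(unknown, collapse = ", "))
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# Resolve raw (possibly transcript-overlapping) gene features into a disjoint
# tiling with precedence CDS > UTR > intron > intergenic.
.resolve_annotation <- function(annotation, chrom_lengths) {
  cats <- c("CDS", "UTR", "intron")
  if (!all(annotation$category %in% cats))
    stop("annotation categories must be one of: ", paste(cats, collapse = ", "))
  genome_gr <- GenomicRanges::GRanges(
    names(chrom_lengths), IRanges::IRanges(1L, chrom_lengths))
  taken <- GenomicRanges::GRanges()
  pieces <- list()
  for (cat in cats) {
    sub <- annotation[annotation$category == cat, , drop = FALSE]
    if (!nrow(sub)) next
    gr <- .as_granges(sub, chrom_lengths)
    if (any(GenomicRanges::start(gr) < 1L) ||
        any(GenomicRanges::end(gr) >
              chrom_lengths[as.character(GenomicRanges::seqnames(gr))]))
      stop("annotation intervals must lie within the genome")
    red <- GenomicRanges::reduce(gr)
    if (sum(IRanges::width(red)) != sum(IRanges::width(gr)))
      stop("overlapping same-category intervals in '", cat, "' annotation")
    kept <- GenomicRanges::setdiff(red, taken)
    if (length(kept)) {
      kept$category <- cat
      pieces[[cat]] <- kept
    }
    taken <- GenomicRanges::reduce(c(taken, red))
  }
  inter <- GenomicRanges::setdiff(genome_gr, taken)
  if (length(inter)) {
    inter$category <- "intergenic"
    pieces[["intergenic"]] <- inter
  }
  out <- sort(do.call(c, unname(pieces)))
  out
}

#' @export
print.numt_genome <- function(x, ...) {
  cat("numt_genome:", length(x$chrom_lengths), "nuclear chromosome(s),",
      format(nuclear_size(x), big.mark = ","), "bp nuclear;",
      x$mt_name, "=", x$mt_length, "bp\n")
  if (!is.null(x$annotation)) {
    fr <- category_fractions(x)
    cat("  annotation:", paste(sprintf("%s %.2f%%", names(fr), 100 * fr),
                               collapse = ", "), "\n")
  }
  if (!is.null(x$mask))
    cat("  mask:", sum(IRanges::width(x$mask)), "bp in",
        length(x$mask), "interval(s)\n")
  invisible(x)
}

#' Total nuclear genome size
#' @param model A `numt_genome`.
#' @return Total nuclear length in bp.
#' @export
nuclear_size <- function(model) {
  stopifnot(inherits(model, "numt_genome"))
  sum(model$chrom_lengths)
}

#' Base-pair fraction of each annotation category
#'
#' Fractions of the nuclear genome covered by each category of the resolved
#' annotation tiling. With no annotation the genome is entirely intergenic.
#'
#' @param model A `numt_genome`.
#' @return Named numeric vector over `c("CDS","UTR","intron","intergenic")`
#'   summing to 1.
#' @export
category_fractions <- function(model) {
  stopifnot(inherits(model, "numt_genome"))
  cats <- c("CDS", "UTR", "intron", "intergenic")
  out <- stats::setNames(numeric(4), cats)
  if (is.null(model$annotation)) {
    out["intergenic"] <- 1
    return(out)
  }
  bp <- tapply(IRanges::width(model$annotation),
               model$annotation$category, sum)
  out[names(bp)] <- bp / nuclear_size(model)
  out
}

# Map between per-chromosome coordinates and a single concatenated axis
# (1 .. nuclear_size). Used for uniform placement and permutation shuffles.
.chrom_offsets <- function(model) {
  c(0, cumsum(as.numeric(model$chrom_lengths)))[seq_along(model$chrom_lengths)]
}

.global_to_pos <- function(model, g) {
  offs <- .chrom_offsets(model)
  idx <- findInterval(g - 1, c(offs, nuclear_size(model)),
                      rightmost.closed = TRUE)
  idx[idx > length(offs)] <- length(offs)
  data.frame(chrom = names(model$chrom_lengths)[idx],
             pos = as.integer(g - offs[idx]))
}

.pos_to_global <- function(model, chrom, pos) {
  offs <- stats::setNames(.chrom_offsets(model), names(model$chrom_lengths))
  unname(offs[chrom] + pos)
}

#' Chromosome lengths of the GRCh37 autosomes
#'
#' Convenience preset of the 22 human autosome lengths (GRCh37/hg19), used for
#' human-scale binning and placement simulations.
#'
#' @return Named numeric vector of lengths in bp.
#' @export
grch37_autosomes <- function() {
  c(chr1 = 249250621, chr2 = 243199373, chr3 = 198022430, chr4 = 191154276,
    chr5 = 180915260, chr6 = 171115067, chr7 = 159138663, chr8 = 146364022,
    chr9 = 141213431, chr10 = 135534747, chr11 = 135006516, chr12 = 133851895,
    chr13 = 115169878, chr14 = 107349540, chr15 = 102531392, chr16 = 90354753,
    chr17 = 81195210, chr18 = 78077248, chr19 = 59128983, chr20 = 63025520,
    chr21 = 48129895, chr22 = 51304566)
}

#' Simulate a gene annotation with target base-pair fractions
#'
#' Draws a gene structure (UTR ends, alternating CDS exons and introns,
#' intergenic gaps) along each chromosome so that the genome-wide base-pair
#' fractions approximate the targets. Defaults approximate the human genome:
#' ~63.9% intergenic, ~34.9% intron, with the remainder split between CDS and
#' UTR. Uses the current R random number generator; call [set.seed()] first
#' for reproducibility.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param intergenic,intron,cds,utr Target base-pair fractions (must sum to 1).
#' @param mean_gene_length Mean simulated gene span in bp.
#' @return A `data.frame` with columns `chrom`, `start`, `end`, `category`
#'   suitable for [make_genome_model()].
#' @export
simulate_annotation <- function(chrom_lengths,
                                intergenic = 0.6392, intron = 0.3492,
                                cds = 0.0075, utr = 0.0041,
                                mean_gene_length = 3e4) {
  fr <- c(intergenic = intergenic, intron = intron, cds = cds, utr = utr)
  if (abs(sum(fr) - 1) > 1e-8) stop("target fractions must sum to 1")
  genic <- 1 - intergenic
  rows <- list()
  for (ch in names(chrom_lengths)) {
    len <- chrom_lengths[[ch]]
    pos <- 1
    mean_gap <- mean_gene_length * intergenic / genic
    repeat {
      gap <- round(stats::rexp(1, 1 / mean_gap))
      gstart <- pos + gap
      glen <- max(600, round(stats::rlnorm(
        1, log(mean_gene_length) - 0.32, 0.8)))
      if (gstart + glen - 1 > len) break
      rows[[length(rows) + 1L]] <- .simulate_gene(ch, gstart, glen, fr, genic)
      pos <- gstart + glen
    }
  }
  if (!length(rows))
    stop("no genes fit on the supplied chromosomes; increase their lengths")
  do.call(rbind, rows)
}

.simulate_gene <- function(chrom, start, glen, fr, genic) {
  utr_bp <- max(2, round(glen * fr[["utr"]] / genic))
  cds_bp <- max(2, round(glen * fr[["cds"]] / genic))
  intron_bp <- glen - utr_bp - cds_bp
  n_exon <- max(1L, round(cds_bp / 150))
  exon_len <- .split_int(cds_bp, n_exon)
  intron_len <- .split_int(intron_bp, n_exon + 1L)
  utr5 <- utr_bp %/% 2L
  utr3 <- utr_bp - utr5
  lens <- c(utr5,
            as.vector(rbind(intron_len[seq_len(n_exon)], exon_len)),
            intron_len[n_exon + 1L], utr3)
  cats <- c("UTR", rep(c("intron", "CDS"), n_exon), "intron", "UTR")
  keep <- lens > 0
  ends <- start - 1L + cumsum(lens[keep])
  starts <- c(start, utils::head(ends, -1L) + 1L)
  data.frame(chrom = chrom, start = starts, end = ends,
             category = cats[keep], row.names = NULL)
}

# Random integer composition of `total` into `k` non-negative parts.
.split_int <- function(total, k) {
  if (k == 1L) return(total)
  if (total <= 0) return(rep(0L, k))
  w <- stats::rgamma(k, 1)
  parts <- floor(total * w / sum(w))
  rem <- total - sum(parts)
  if (rem > 0) parts[seq_len(rem)] <- parts[seq_len(rem)] + 1L
  parts
}
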
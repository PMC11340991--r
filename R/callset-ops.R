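#' Merge per-sample Numt call sets into unified loci
#'
#' Single-linkage (transitive-closure) merging: calls on the same chromosome
#' whose breakpoints are within `window` bp — directly or through a chain —
#' form one locus. The representative breakpoint is the median of member
#' positions. Chains can therefore exceed `window` bp end-to-end; this is
#' the behavior of standard SV merging modules.
#'
#' @param calls A `data.frame` of calls with at least `sample_id`, `chrom`,
#'   `pos` (e.g., the cohort simulator's calls, or rbind-ed caller output),
#'   or a list of such frames.
#' @param window Merge window in bp (default 50, the same proximity used for
#'   population cross-referencing).
#' @return An object of class `numt_unified`: list with `loci`
#'   (`locus_id`, `chrom`, `pos`, `n_samples`, `n_calls`) and `members`
#'   (per input call: `locus_id`, `sample_id`, `chrom`, `pos`, ...).
#' @export
merge_callsets <- function(calls, window = 50) {
  if (is.list(calls) && !is.data.frame(calls))
    calls <- do.call(rbind, calls)
  stopifnot(all(c("sample_id", "chrom", "pos") %in% names(calls)))
  members <- calls[order(calls$chrom, calls$pos), , drop = FALSE]
  if (nrow(members)) {
    same <- c(FALSE, members$chrom[-1] == members$chrom[-nrow(members)])
    gap <- c(Inf, diff(members$pos))
    members$locus_id <- cumsum(!(same & gap <= window))
  } else {
    members$locus_id <- integer(0)
  }
  loci <- if (nrow(members)) {
    agg <- split(members, members$locus_id)
    do.call(rbind, lapply(agg, function(m) data.frame(
      locus_id = m$locus_id[1], chrom = m$chrom[1],
      pos = as.integer(round(stats::median(m$pos))),
      n_samples = length(unique(m$sample_id)), n_calls = nrow(m),
      stringsAsFactors = FALSE)))
  } else {
    data.frame(locus_id = integer(0), chrom = character(0),
               pos = integer(0), n_samples = integer(0),
               n_calls = integer(0))
  }
  rownames(loci) <- rownames(members) <- NULL
  structure(list(loci = loci, members = members, window = window),
            class = "numt_unified")
}

#' @export
print.numt_unified <- function(x, ...) {
  cat("numt_unified:", nrow(x$loci), "loci from", nrow(x$members),
      "calls in", length(unique(x$members$sample_id)), "samples (window",
      x$window, "bp)\n")
  invisible(x)
}

#' Presence matrix of a unified call set
#' @param unified A `numt_unified`.
#' @return Logical matrix loci x samples.
#' @export
presence_matrix <- function(unified) {
  stopifnot(inherits(unified, "numt_unified"))
  samples <- sort(unique(unified$members$sample_id))
  m <- matrix(FALSE, nrow(unified$loci), length(samples),
              dimnames = list(unified$loci$locus_id, samples))
  idx <- cbind(match(unified$members$locus_id, unified$loci$locus_id),
               match(unified$members$sample_id, samples))
  m[idx] <- TRUE
  m
}

.subset_unified <- function(unified, keep_loci) {
  out <- unified
  out$loci <- unified$loci[unified$loci$locus_id %in% keep_loci, ,
                           drop = FALSE]
  out$members <- unified$members[unified$members$locus_id %in% keep_loci, ,
                                 drop = FALSE]
  rownames(out$loci) <- rownames(out$members) <- NULL
  out
}

#' Remove loci matching population-reference Numts
#'
#' Drops unified loci whose representative breakpoint falls within
#' `window` bp of any entry of a population-scale Numt reference list,
#' treating them as germline polymorphic insertions.
#'
#' @param unified A `numt_unified`.
#' @param refs Population reference `data.frame` with `chrom` and `pos`
#'   (e.g., the cohort simulator's `pop_ref`).
#' @param window Match window in bp.
#' @return The filtered `numt_unified`, with attribute `"n_removed"`.
#' @export
filter_population <- function(unified, refs, window = 50) {
  stopifnot(inherits(unified, "numt_unified"))
  if (is.null(refs) || !nrow(refs)) {
    warning("empty population reference list; returning input unchanged")
    attr(unified, "n_removed") <- 0L
    return(unified)
  }
  hit <- vapply(seq_len(nrow(unified$loci)), function(i) {
    r <- refs[refs$chrom == unified$loci$chrom[i], , drop = FALSE]
    nrow(r) > 0 && any(abs(r$pos - unified$loci$pos[i]) <= window)
  }, logical(1))
  out <- .subset_unified(unified, unified$loci$locus_id[!hit])
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Extract group-exclusive (tissue- or cell-line-specific) loci
#'
#' Retains loci whose carrier samples all share a single group label
#' (tissue, or donor-by-treatment cell line). Loci seen in more than one
#' group are treated as germline or early-somatic and dropped.
#'
#' @param unified A `numt_unified`.
#' @param meta Sample sheet with `sample_id` and the grouping column.
#' @param group_col Name of the grouping column in `meta` (default
#'   `"tissue"`).
#' @param max_carriers Optionally also drop loci carried by more than this
#'   many samples even within one group (stricter germline screen;
#'   default `Inf` retains recurrent within-group loci).
#' @return The exclusive `numt_unified`; its `loci` gain a `group` column.
#' @export
exclusive_calls <- function(unified, meta, group_col = "tissue",
                            max_carriers = Inf) {
  stopifnot(inherits(unified, "numt_unified"),
            all(c("sample_id", group_col) %in% names(meta)))
  grp <- meta[[group_col]][match(unified$members$sample_id, meta$sample_id)]
  if (anyNA(grp)) {
    bad <- unique(unified$members$sample_id[is.na(grp)])
    stop("sample(s) missing from the sample sheet: ",
         paste(utils::head(bad, 5), collapse = ", "))
  }
  by_locus <- split(grp, unified$members$locus_id)
  n_car <- vapply(split(unified$members$sample_id, unified$members$locus_id),
                  function(s) length(unique(s)), integer(1))
  excl <- vapply(by_locus, function(g) length(unique(g)) == 1L, logical(1))
  keep_ids <- as.integer(names(by_locus))[excl & n_car <= max_carriers]
  out <- .subset_unified(unified, keep_ids)
  out$loci$group <- vapply(
    split(grp, unified$members$locus_id)[as.character(out$loci$locus_id)],
    function(g) g[1], character(1))
  out
}

#' Per-sample total and exclusive call counts
#'
#' @param unified A `numt_unified` (typically after population filtering).
#' @param meta Sample sheet with `sample_id` and the grouping column; samples
#'   without calls are included with zero counts.
#' @param group_col Grouping column used for exclusivity.
#' @return `data.frame(sample_id, group, total, exclusive)`.
#' @export
per_sample_counts <- function(unified, meta, group_col = "tissue") {
  stopifnot(inherits(unified, "numt_unified"))
  excl <- exclusive_calls(unified, meta, group_col = group_col)
  tot <- table(unified$members$sample_id)
  exc <- table(excl$members$sample_id)
  data.frame(
    sample_id = meta$sample_id,
    group = meta[[group_col]],
    total = as.integer(ifelse(is.na(tot[meta$sample_id]), 0,
                              tot[meta$sample_id])),
    exclusive = as.integer(ifelse(is.na(exc[meta$sample_id]), 0,
                                  exc[meta$sample_id])),
    stringsAsFactors = FALSE)
}

#' Write Numt calls as a VCF 4.2 file
#'
#' One record per call with INFO fields MSTART/MEND/MLEN (mtDNA segment),
#' SR (supporting pairs), DP (local depth), VAF, and CIPOS, and the caller's
#' FILTER vocabulary.
#'
#' @param calls Caller output ([call_numts()]) or any frame with `chrom`,
#'   `pos` and optionally the INFO columns.
#' @param path Output path.
#' @param model A `numt_genome` for the contig header lines.
#' @param sample_id Sample name written in the header.
#' @return `path`, invisibly.
#' @export
write_numt_vcf <- function(calls, path, model, sample_id = NULL) {
  stopifnot(inherits(model, "numt_genome"))
  g <- function(col, default = NA) {
    if (col %in% names(calls)) calls[[col]] else rep(default, nrow(calls))
  }
  info <- sprintf("MSTART=%s;MEND=%s;MLEN=%s;SR=%s;DP=%s;VAF=%s;CIPOS=%s,%s",
                  g("mt_start"), g("mt_end"), g("length"), g("support", 0),
                  g("depth", 0), g("vaf", 0), g("ci_lo", 0), g("ci_hi", 0))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=numtogenesis",
           if (!is.null(sample_id)) paste0("##sample=", sample_id),
           sprintf("##contig=<ID=%s,length=%d>",
                   c(names(model$chrom_lengths), model$mt_name),
                   as.integer(c(model$chrom_lengths, model$mt_length))),
           "##INFO=<ID=MSTART,Number=1,Type=Integer,Description=\"mtDNA segment start (1-based)\">",
           "##INFO=<ID=MEND,Number=1,Type=Integer,Description=\"mtDNA segment end (1-based)\">",
           "##INFO=<ID=MLEN,Number=1,Type=Integer,Description=\"Inserted mtDNA length (bp)\">",
           "##INFO=<ID=SR,Number=1,Type=Integer,Description=\"Supporting read pairs\">",
           "##INFO=<ID=DP,Number=1,Type=Float,Description=\"Local read depth\">",
           "##INFO=<ID=VAF,Number=1,Type=Float,Description=\"Variant allele fraction\">",
           "##INFO=<ID=CIPOS,Number=2,Type=Integer,Description=\"Breakpoint confidence interval\">",
           "##FILTER=<ID=min_support,Description=\"Fewer than 4 supporting pairs\">",
           "##FILTER=<ID=min_depth,Description=\"Local depth below 5x\">",
           "##FILTER=<ID=min_qual,Description=\"Call quality below Phred 50\">",
           "##FILTER=<ID=one_sided,Description=\"Evidence on one side only\">",
           "##FILTER=<ID=anchor_lt150,Description=\"Anchored nuclear span below 150 bp\">",
           "##ALT=<ID=INS:MT,Description=\"Mitochondrial DNA insertion\">",
           "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  body <- if (nrow(calls)) {
    sprintf("%s\t%d\t%s\t%s\t%s\t%s\t%s\t%s",
            calls$chrom, as.integer(calls$pos),
            sprintf("NUMT%04d", seq_len(nrow(calls))), "N", "<INS:MT>",
            format(g("qual", 0)), g("filter", "PASS"), info)
  } else {
    character(0)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a Numt VCF back into a calls frame
#'
#' @param path Path to a VCF written by [write_numt_vcf()] (or any VCF with
#'   the same INFO keys).
#' @return A calls `data.frame`.
#' @export
read_numt_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
  if (!nrow(fix))
    return(data.frame(chrom = character(0), pos = integer(0),
                      filter = character(0)))
  num <- function(key) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = key)))
  data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
             qual = suppressWarnings(as.numeric(fix$QUAL)),
             filter = fix$FILTER,
             mt_start = as.integer(num("MSTART")),
             mt_end = as.integer(num("MEND")),
             length = as.integer(num("MLEN")),
             support = as.integer(num("SR")),
             depth = num("DP"), vaf = num("VAF"),
             stringsAsFactors = FALSE)
}
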
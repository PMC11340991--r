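#' Caller thresholds and tuning parameters
#'
#' Defaults follow the detection criteria used for non-reference Numt
#' discovery from discordant read pairs: nuclear anchors require MAPQ >= 10,
#' PASS calls require call quality >= 50 (Phred), >= 4 supporting read pairs,
#' and >= 5x read depth around the insertion point; contamination screening
#' requires >= 150 bp of anchored nuclear sequence.
#'
#' @param min_mapq Minimum anchor mapping quality.
#' @param min_support Minimum supporting read pairs for PASS.
#' @param min_depth Minimum local depth (fold) for PASS.
#' @param min_qual Minimum Phred-scaled call quality for PASS.
#' @param min_anchor Minimum anchored nuclear span in bp for PASS.
#' @param cluster_window Single-linkage clustering window for anchors, bp
#'   (about one fragment length plus three s.d.).
#' @param pairing_window Maximum distance between a forward and a reverse
#'   cluster paired into one event, bp.
#' @param depth_flank Half-width of the window around the breakpoint over
#'   which the local depth median is taken, bp.
#' @param vaf_denominator `"local"` (median depth around the breakpoint) or
#'   `"sample_mean"` (genome-wide mean coverage, which must then be given as
#'   `sample_mean_coverage`).
#' @param sample_mean_coverage Optional genome-wide mean coverage.
#' @return A list of class `numt_caller_params`.
#' @export
caller_params <- function(min_mapq = 10, min_support = 4, min_depth = 5,
                          min_qual = 50, min_anchor = 150,
                          cluster_window = 750, pairing_window = 750,
                          depth_flank = 300,
                          vaf_denominator = c("local", "sample_mean"),
                          sample_mean_coverage = NULL) {
  vaf_denominator <- match.arg(vaf_denominator)
  if (vaf_denominator == "sample_mean" && is.null(sample_mean_coverage))
    stop("'sample_mean_coverage' is required for vaf_denominator = 'sample_mean'")
  structure(list(min_mapq = min_mapq, min_support = min_support,
                 min_depth = min_depth, min_qual = min_qual,
                 min_anchor = min_anchor, cluster_window = cluster_window,
                 pairing_window = pairing_window, depth_flank = depth_flank,
                 vaf_denominator = vaf_denominator,
                 sample_mean_coverage = sample_mean_coverage),
            class = "numt_caller_params")
}

#' Cluster discordant mtDNA-anchored read pairs
#'
#' Retains nuclear reads with MAPQ at or above the threshold whose mate maps
#' to the mitochondrial contig, and groups them into strand-aware
#' single-linkage clusters: consecutive retained anchors on the same
#' chromosome and strand closer than `cluster_window` bp join one cluster.
#' Each retained read belongs to exactly one cluster.
#'
#' @param records Alignment records from [read_sam()] or
#'   [alignment_records()], sorted by (chromosome, position).
#' @param model A `numt_genome` (supplies the mitochondrial contig name).
#' @param params A [caller_params()].
#' @return The retained records with an added `cluster_id` column; class
#'   `numt_clusters` with the parameters attached as attributes.
#' @export
scan_discordant <- function(records, model, params = caller_params()) {
  stopifnot(inherits(model, "numt_genome"))
  .check_sorted(records)
  keep <- records$chrom != model$mt_name &
    records$mapq >= params$min_mapq &
    records$mate_chrom == model$mt_name
  sup <- records[keep, , drop = FALSE]
  if (nrow(sup)) {
    sup <- sup[order(match(sup$chrom, unique(sup$chrom)), sup$strand,
                     sup$pos), , drop = FALSE]
    grp <- paste(sup$chrom, sup$strand)
    new_grp <- c(TRUE, grp[-1] != grp[-nrow(sup)])
    gap <- c(0, diff(sup$pos))
    new_cl <- new_grp | gap > params$cluster_window
    sup$cluster_id <- cumsum(new_cl)
    rownames(sup) <- NULL
  } else {
    sup$cluster_id <- integer(0)
  }
  structure(sup, class = c("numt_clusters", "data.frame"),
            params = params, mt_name = model$mt_name)
}

.check_sorted <- function(records) {
  if (!nrow(records)) return(invisible(TRUE))
  ch <- records$chrom
  runs <- rle(ch)$values
  if (anyDuplicated(runs))
    stop("input not sorted: chromosome '", runs[anyDuplicated(runs)],
         "' appears in non-contiguous blocks")
  bad <- which(c(FALSE, diff(records$pos) < 0) &
                 c(FALSE, ch[-1] == ch[-length(ch)]))
  if (length(bad))
    stop("input not sorted: record ", bad[1], " (", ch[bad[1]], ":",
         records$pos[bad[1]], ") is before its predecessor")
  invisible(TRUE)
}

#' Call Numt insertions from discordant clusters
#'
#' Pairs forward- and reverse-strand clusters within `pairing_window` into
#' single insertion events, estimates the breakpoint from the innermost
#' anchor edges (forward cluster: rightmost anchor end + 1; reverse cluster:
#' leftmost anchor start; paired: their midpoint, with a confidence interval
#' spanning both estimates), reconstructs the mtDNA segment from the span of
#' mate positions, and applies the quality, support, depth and anchored-span
#' filters. Calls failing a threshold are emitted with non-PASS filter flags.
#'
#' @param clusters Output of [scan_discordant()].
#' @param depth Per-base coverage: either a [coverage_track()] list or a
#'   single number used as a flat depth.
#' @param model A `numt_genome`.
#' @param params A [caller_params()].
#' @param sample_id Sample identifier stored in the calls.
#' @return A `data.frame` of calls: `sample_id`, `chrom`, `pos`, `ci_lo`,
#'   `ci_hi`, `mt_start`, `mt_end`, `length`, `support`, `depth`, `qual`,
#'   `vaf`, `anchored_span`, `filter` (`"PASS"` or semicolon-joined flags
#'   among `min_support`, `min_depth`, `min_qual`, `one_sided`,
#'   `anchor_lt150`).
#' @export
call_numts <- function(clusters, depth, model, params = attr(clusters, "params"),
                       sample_id = "sample") {
  stopifnot(inherits(clusters, "numt_clusters"))
  if (is.null(params)) params <- caller_params()
  cl <- as.data.frame(clusters)
  empty <- data.frame(sample_id = character(0), chrom = character(0),
                      pos = integer(0), ci_lo = integer(0),
                      ci_hi = integer(0), mt_start = integer(0),
                      mt_end = integer(0), length = integer(0),
                      support = integer(0), depth = numeric(0),
                      qual = numeric(0), vaf = numeric(0),
                      anchored_span = integer(0), filter = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(cl)) return(empty)

  ids <- unique(cl$cluster_id)
  summ <- do.call(rbind, lapply(ids, function(id) {
    sub <- cl[cl$cluster_id == id, , drop = FALSE]
    fwd <- sub$strand[1] == "+"
    data.frame(cluster_id = id, chrom = sub$chrom[1], fwd = fwd,
               bp = if (fwd) max(sub$pos + sub$span - 1L) + 1L
                    else min(sub$pos),
               n = nrow(sub), stringsAsFactors = FALSE)
  }))

  # greedy nearest-distance pairing of forward with reverse clusters
  pairs <- list()
  used_r <- integer(0)
  for (ch in unique(summ$chrom)) {
    f <- summ[summ$chrom == ch & summ$fwd, , drop = FALSE]
    r <- summ[summ$chrom == ch & !summ$fwd, , drop = FALSE]
    if (nrow(f) && nrow(r)) {
      cand <- expand.grid(fi = seq_len(nrow(f)), ri = seq_len(nrow(r)))
      cand$d <- abs(f$bp[cand$fi] - r$bp[cand$ri])
      cand <- cand[cand$d <= params$pairing_window, , drop = FALSE]
      cand <- cand[order(cand$d), , drop = FALSE]
      used_f <- logical(nrow(f)); used_rl <- logical(nrow(r))
      for (k in seq_len(nrow(cand))) {
        fi <- cand$fi[k]; ri <- cand$ri[k]
        if (!used_f[fi] && !used_rl[ri]) {
          used_f[fi] <- TRUE; used_rl[ri] <- TRUE
          pairs[[length(pairs) + 1L]] <-
            c(f$cluster_id[fi], r$cluster_id[ri])
        }
      }
    }
  }
  paired_ids <- unlist(pairs)
  singles <- setdiff(ids, paired_ids)
  events <- c(pairs, as.list(singles))

  calls <- lapply(events, function(ev_ids) {
    sub <- cl[cl$cluster_id %in% ev_ids, , drop = FALSE]
    one_sided <- length(ev_ids) == 1L
    ests <- summ$bp[match(ev_ids, summ$cluster_id)]
    bp <- as.integer(floor(mean(range(ests))))
    ci <- as.integer(range(ests) - bp)
    support <- nrow(sub)
    qual <- min(sum(sub$mapq), 99)
    mt_start <- min(sub$mate_pos)
    mt_end <- min(max(sub$mate_pos) + max(sub$read_length) - 1L,
                  model$mt_length)
    loc_depth <- .local_depth(depth, sub$chrom[1], bp, params$depth_flank,
                              model)
    denom <- if (params$vaf_denominator == "local") loc_depth
             else params$sample_mean_coverage
    vaf <- if (denom > 0) compute_vaf(support, denom) else NA_real_
    span <- anchored_span_check(sub, min_anchor = params$min_anchor)
    flags <- c(
      if (support < params$min_support) "min_support",
      if (loc_depth < params$min_depth) "min_depth",
      if (qual < params$min_qual) "min_qual",
      if (one_sided) "one_sided",
      if (!span$pass) "anchor_lt150")
    data.frame(sample_id = sample_id, chrom = sub$chrom[1], pos = bp,
               ci_lo = ci[1], ci_hi = ci[2],
               mt_start = as.integer(mt_start), mt_end = as.integer(mt_end),
               length = as.integer(mt_end - mt_start + 1L),
               support = as.integer(support), depth = loc_depth,
               qual = qual, vaf = vaf,
               anchored_span = as.integer(span$span),
               filter = if (length(flags)) paste(flags, collapse = ";")
                        else "PASS",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, calls)
  out <- out[order(match(out$chrom, names(model$chrom_lengths)), out$pos), ]
  rownames(out) <- NULL
  out
}

.local_depth <- function(depth, chrom, bp, flank, model) {
  if (is.numeric(depth) && length(depth) == 1L) return(depth)
  if (is.null(depth[[chrom]]))
    stop("missing depth track over cluster on ", chrom)
  len <- length(depth[[chrom]])
  lo <- max(1L, bp - flank)
  hi <- min(len, bp + flank)
  if (lo > hi) stop("missing depth over cluster at ", chrom, ":", bp)
  stats::median(as.integer(S4Vectors::window(depth[[chrom]], lo, hi)))
}

#' Variant allele fraction of a call
#'
#' Supporting read-pair count divided by read coverage, clipped to `[0, 1]`.
#'
#' @param supporting Number of supporting read pairs.
#' @param coverage Fold read coverage (local or genome-wide; must be > 0).
#' @return VAF in `[0, 1]`.
#' @examples
#' compute_vaf(5, 45)
#' @export
compute_vaf <- function(supporting, coverage) {
  if (any(coverage <= 0)) stop("'coverage' must be positive")
  if (any(supporting < 0)) stop("'supporting' must be non-negative")
  pmin(pmax(supporting / coverage, 0), 1)
}

#' Anchored nuclear span of a call's supporting reads
#'
#' Length of the union of the nuclear-aligned segments of the supporting
#' reads. Calls anchored by fewer than `min_anchor` bp of chromosomal
#' sequence are compatible with contaminant (e.g., bacterial) inserts rather
#' than genuine nuclear integration, and fail this check.
#'
#' @param supporting Alignment records of the supporting nuclear anchors
#'   (needs `pos` and `span`).
#' @param min_anchor Minimum anchored span in bp.
#' @return A list with `pass` (logical) and `span` (bp of anchored union).
#' @export
anchored_span_check <- function(supporting, min_anchor = 150) {
  if (!nrow(supporting) || all(supporting$span == 0))
    return(list(pass = FALSE, span = 0L))
  ir <- IRanges::IRanges(supporting$pos, width = supporting$span)
  span <- sum(IRanges::width(IRanges::reduce(ir)))
  list(pass = span >= min_anchor, span = span)
}

#' Detect Numts from a SAM file or alignment records
#'
#' Convenience wrapper: normalize/read alignments, compute the coverage
#' track, cluster discordant pairs, and call insertions.
#'
#' @param x Path to a SAM file, a simulator frame from
#'   [simulate_read_evidence()], or normalized alignment records.
#' @param model A `numt_genome`.
#' @param params A [caller_params()].
#' @param sample_id Sample identifier.
#' @return Calls as from [call_numts()].
#' @export
detect_numts <- function(x, model, params = caller_params(),
                         sample_id = "sample") {
  records <- if (is.character(x)) read_sam(x)
             else if (!is.null(x$rnext)) alignment_records(x)
             else x
  track <- coverage_track(records, model)
  cl <- scan_discordant(records, model, params)
  call_numts(cl, track, model, params, sample_id = sample_id)
}
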
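#' Paired-end fragment model
#'
#' Gaussian fragment (insert) size model with fixed read length, truncated
#' below at twice the read length. Presets mirror common short-read layouts:
#' `"brain"` 2 x 151 bp, `"fibroblast"` 2 x 149 bp.
#'
#' @param mean,sd Fragment length mean and standard deviation in bp.
#' @param read_length Read length in bp.
#' @param preset Optional preset overriding `read_length`.
#' @return An object of class `numt_fragment_model`.
#' @export
fragment_model <- function(mean = 450, sd = 100, read_length = 151,
                           preset = c("none", "brain", "fibroblast")) {
  preset <- match.arg(preset)
  if (preset == "brain") read_length <- 151L
  if (preset == "fibroblast") read_length <- 149L
  if (mean <= 2 * read_length)
    stop("mean fragment length must exceed twice the read length")
  structure(list(mean = mean, sd = sd, read_length = as.integer(read_length),
                 preset = preset),
            class = "numt_fragment_model")
}

#' Simulate junction-spanning read-pair evidence for one insertion
#'
#' Simulates paired-end sequencing of the region around a planted Numt
#' insertion. Molecules are drawn at a fragment rate matching the requested
#' fold-coverage; a fraction `event$vaf` of molecules carry the insertion
#' allele. Reads from carrier molecules that straddle an insertion junction
#' are emitted as discordant pairs: the nuclear-anchored mate keeps its
#' nuclear position (junction overhang soft-clipped in the CIGAR), and a mate
#' whose bases are mostly insert-derived is mapped to the mitochondrial
#' contig inside the inserted segment. Non-carrier molecules yield ordinary
#' concordant pairs. Optional background chimeric pairs (one nuclear read
#' with a random mitochondrial mate) are added at `chimeric_rate` per bp.
#'
#' @param model A `numt_genome`.
#' @param event A one-row event `data.frame` as produced by
#'   [sample_numt_event()], with a `vaf` column (carrier fraction).
#' @param depth Fold read coverage of the region; `0` yields no records.
#' @param frag_model A [fragment_model()].
#' @param window Half-width in bp of the simulated region around the
#'   insertion point.
#' @param chimeric_rate Expected background chimeric pairs per bp of region.
#' @param mapq Mapping quality assigned to uniquely-mapped reads.
#' @param keep_molecules If `TRUE`, attach the underlying molecule table as
#'   attribute `"molecules"` (`start`, `frag_length`, `carrier`) for
#'   cross-checking.
#' @return A `data.frame` of SAM-style alignment records (columns `qname`,
#'   `flag`, `rname`, `pos`, `mapq`, `cigar`, `rnext`, `pnext`, `tlen`),
#'   coordinate-sorted. Write with [write_sam()].
#' @export
simulate_read_evidence <- function(model, event, depth,
                                   frag_model = fragment_model(),
                                   window = 1000, chimeric_rate = 0,
                                   mapq = 60, keep_molecules = FALSE) {
  stopifnot(inherits(model, "numt_genome"),
            inherits(frag_model, "numt_fragment_model"))
  if (depth < 0) stop("'depth' must be non-negative")
  lr <- frag_model$read_length
  if (lr >= frag_model$mean) stop("read length must be below mean fragment length")
  empty <- data.frame(qname = character(0), flag = integer(0),
                      rname = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      rnext = character(0), pnext = integer(0),
                      tlen = integer(0), stringsAsFactors = FALSE)
  if (depth == 0) {
    if (keep_molecules) attr(empty, "molecules") <-
        data.frame(start = integer(0), frag_length = integer(0),
                   carrier = logical(0))
    return(empty)
  }
  bp <- event$pos            # insertion falls between bp and bp + 1
  L <- event$length
  chrom <- event$chrom
  clen <- model$chrom_lengths[[chrom]]
  f_max <- frag_model$mean + 4 * frag_model$sd
  lo <- max(1, bp - window - f_max)
  hi <- min(clen, bp + window)
  rate <- depth / (2 * lr)   # fragments starting per bp, both haplotypes
  # non-carrier molecules live on the reference region; carrier molecules on
  # the ALT haplotype, whose coordinate axis additionally spans the insert
  n_nc <- stats::rpois(1, (1 - event$vaf) * rate * (hi - lo + 1))
  n_c <- stats::rpois(1, event$vaf * rate * (hi - lo + 1 + L))
  starts <- c(floor(stats::runif(n_nc, lo, hi + 1)),
              floor(stats::runif(n_c, lo, hi + L + 1)))
  n_frag <- n_nc + n_c
  flen <- pmax(2L * lr + 10L,
               round(stats::rnorm(n_frag, frag_model$mean, frag_model$sd)))
  carrier <- rep(c(FALSE, TRUE), c(n_nc, n_c))
  mol <- data.frame(start = as.integer(starts),
                    frag_length = as.integer(flen), carrier = carrier)

  recs <- vector("list", n_frag)
  for (i in seq_len(n_frag)) {
    recs[[i]] <- .place_pair(model, chrom, bp, L, event$mt_start,
                             mol$start[i], mol$frag_length[i],
                             mol$carrier[i], lr, mapq,
                             qname = sprintf("frag%05d", i))
  }
  out <- do.call(rbind, recs)

  if (chimeric_rate > 0) {
    n_noise <- stats::rpois(1, chimeric_rate * (hi - lo + 1))
    if (n_noise > 0) {
      npos <- as.integer(floor(stats::runif(n_noise, lo, hi + 1)))
      mpos <- as.integer(ceiling(stats::runif(n_noise) * model$mt_length))
      for (k in seq_len(n_noise)) {
        out <- rbind(out, .pair_records(
          qname = sprintf("chim%05d", k), chrom1 = chrom, pos1 = npos[k],
          cigar1 = paste0(lr, "M"), strand1 = "+",
          chrom2 = model$mt_name, pos2 = mpos[k],
          cigar2 = paste0(lr, "M"), strand2 = "-",
          mapq = mapq, proper = FALSE, tlen = 0L))
      }
    }
  }
  out <- out[order(match(out$rname, c(names(model$chrom_lengths),
                                      model$mt_name)), out$pos), ]
  rownames(out) <- NULL
  if (keep_molecules) attr(out, "molecules") <- mol
  out
}

# Map both reads of one molecule from the carrier/reference haplotype back to
# reference coordinates. ALT haplotype coordinates: ... bp | insert (L) | bp+1 ...
.place_pair <- function(model, chrom, bp, L, mt_start, s, flen, carrier,
                        lr, mapq, qname) {
  r1 <- c(s, s + lr - 1L)                    # leftmost read, + strand
  r2 <- c(s + flen - lr, s + flen - 1L)      # rightmost read, - strand
  if (!carrier) {
    return(.pair_records(qname, chrom, r1[1], paste0(lr, "M"), "+",
                         chrom, r2[1], paste0(lr, "M"), "-", mapq,
                         proper = TRUE, tlen = flen))
  }
  m1 <- .map_read(model, chrom, bp, L, mt_start, r1, lr)
  m2 <- .map_read(model, chrom, bp, L, mt_start, r2, lr)
  proper <- m1$chrom == m2$chrom && m1$chrom == chrom
  .pair_records(qname, m1$chrom, m1$pos, m1$cigar, "+",
                m2$chrom, m2$pos, m2$cigar, "-", mapq,
                proper = proper, tlen = if (proper) flen else 0L)
}

# One read [a, b] in ALT coordinates -> (chrom, pos, cigar) in reference
# coordinates. Insert occupies ALT [bp + 1, bp + L]. A read whose bases are
# mostly insert-derived maps to the mtDNA contig; junction overhang is
# soft-clipped on nuclear-anchored reads.
.map_read <- function(model, chrom, bp, L, mt_start, r, lr) {
  a <- r[1]; b <- r[2]
  ins_lo <- bp + 1; ins_hi <- bp + L
  ins_bases <- max(0, min(b, ins_hi) - max(a, ins_lo) + 1)
  if (ins_bases > lr / 2) {
    off <- max(a, ins_lo) - ins_lo
    mt_pos <- ((mt_start - 1 + off) %% model$mt_length) + 1
    m <- min(ins_bases, lr)
    clip_l <- max(0, ins_lo - a)
    clip_r <- lr - m - clip_l
    cigar <- paste0(if (clip_l > 0) paste0(clip_l, "S"), m, "M",
                    if (clip_r > 0) paste0(clip_r, "S"))
    return(list(chrom = model$mt_name, pos = as.integer(mt_pos),
                cigar = cigar))
  }
  if (b <= bp)                       # fully in left nuclear flank
    return(list(chrom = chrom, pos = as.integer(a), cigar = paste0(lr, "M")))
  if (a > ins_hi)                    # fully in right nuclear flank
    return(list(chrom = chrom, pos = as.integer(a - L),
                cigar = paste0(lr, "M")))
  if (a <= bp) {                     # straddles left junction, mostly nuclear
    m <- bp - a + 1
    if (b > ins_hi) {
      # sub-read-length insert fully contained: insertion CIGAR across it
      m2 <- b - ins_hi
      return(list(chrom = chrom, pos = as.integer(a),
                  cigar = paste0(m, "M", ins_bases, "I", m2, "M")))
    }
    return(list(chrom = chrom, pos = as.integer(a),
                cigar = paste0(m, "M", lr - m, "S")))
  }
  # starts inside the insert, mostly right-flank nuclear
  m <- b - ins_hi
  list(chrom = chrom, pos = as.integer(bp + 1),
       cigar = paste0(lr - m, "S", m, "M"))
}

.pair_records <- function(qname, chrom1, pos1, cigar1, strand1,
                          chrom2, pos2, cigar2, strand2, mapq,
                          proper, tlen) {
  f1 <- 1L + (if (proper) 2L else 0L) + (if (strand1 == "-") 16L else 0L) +
    (if (strand2 == "-") 32L else 0L) + 64L
  f2 <- 1L + (if (proper) 2L else 0L) + (if (strand2 == "-") 16L else 0L) +
    (if (strand1 == "-") 32L else 0L) + 128L
  rnext1 <- if (chrom2 == chrom1) "=" else chrom2
  rnext2 <- if (chrom1 == chrom2) "=" else chrom1
  data.frame(
    qname = c(qname, qname), flag = c(f1, f2),
    rname = c(chrom1, chrom2), pos = c(as.integer(pos1), as.integer(pos2)),
    mapq = as.integer(mapq), cigar = c(cigar1, cigar2),
    rnext = c(rnext1, rnext2), pnext = c(as.integer(pos2), as.integer(pos1)),
    tlen = c(as.integer(tlen), -as.integer(tlen)),
    stringsAsFactors = FALSE)
}

#' Write alignment records as a SAM file
#'
#' Emits a coordinate-sorted SAM file with `@HD`/`@SQ` headers covering all
#' nuclear chromosomes and the mitochondrial contig of `model`.
#'
#' @param aln Alignment `data.frame` from [simulate_read_evidence()] (or any
#'   frame with the nine mandatory SAM columns used there).
#' @param path Output file path.
#' @param model A `numt_genome` supplying the sequence dictionary.
#' @return `path`, invisibly.
#' @export
write_sam <- function(aln, path, model) {
  stopifnot(inherits(model, "numt_genome"))
  seqs <- c(model$chrom_lengths,
            stats::setNames(model$mt_length, model$mt_name))
  hdr <- c("@HD\tVN:1.6\tSO:coordinate",
           sprintf("@SQ\tSN:%s\tLN:%d", names(seqs), as.integer(seqs)))
  aln <- aln[order(match(aln$rname, names(seqs)), aln$pos), , drop = FALSE]
  body <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t%d\t*\t*",
                  aln$qname, aln$flag, aln$rname, aln$pos, aln$mapq,
                  aln$cigar, aln$rnext, aln$pnext, aln$tlen)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a SAM file into alignment records
#'
#' Converts via BAM (Rsamtools) and returns the normalized alignment-record
#' frame used by the caller: one row per mapped read with its strand, CIGAR,
#' reference span and mate location.
#'
#' @param path Path to a SAM file.
#' @return A `data.frame` with columns `qname`, `flag`, `chrom`, `pos`,
#'   `strand`, `mapq`, `cigar`, `read_length`, `span` (aligned reference
#'   span in bp), `mate_chrom`, `mate_pos`.
#' @export
read_sam <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "mapq", "cigar", "mrnm", "mpos",
                                        "qwidth", "strand"))
  x <- Rsamtools::scanBam(bam, param = p)[[1]]
  df <- data.frame(qname = x$qname, flag = x$flag,
                   chrom = as.character(x$rname), pos = x$pos,
                   strand = as.character(x$strand), mapq = x$mapq,
                   cigar = x$cigar, read_length = x$qwidth,
                   span = GenomicAlignments::cigarWidthAlongReferenceSpace(
                     x$cigar),
                   mate_chrom = as.character(x$mrnm), mate_pos = x$mpos,
                   stringsAsFactors = FALSE)
  df[order(match(df$chrom, unique(df$chrom)), df$pos), , drop = FALSE]
}

#' Normalize simulator records into alignment records
#'
#' In-memory counterpart of [read_sam()] for frames produced by
#' [simulate_read_evidence()].
#'
#' @param aln Simulator alignment `data.frame`.
#' @return Alignment records as from [read_sam()].
#' @export
alignment_records <- function(aln) {
  if (!nrow(aln))
    return(data.frame(qname = character(0), flag = integer(0),
                      chrom = character(0), pos = integer(0),
                      strand = character(0), mapq = integer(0),
                      cigar = character(0), read_length = integer(0),
                      span = integer(0), mate_chrom = character(0),
                      mate_pos = integer(0)))
  strand <- ifelse(bitwAnd(aln$flag, 16L) > 0L, "-", "+")
  mate <- ifelse(aln$rnext == "=", aln$rname, aln$rnext)
  data.frame(qname = aln$qname, flag = aln$flag, chrom = aln$rname,
             pos = aln$pos, strand = strand, mapq = aln$mapq,
             cigar = aln$cigar,
             read_length = GenomicAlignments::cigarWidthAlongQuerySpace(
               aln$cigar),
             span = GenomicAlignments::cigarWidthAlongReferenceSpace(
               aln$cigar),
             mate_chrom = mate, mate_pos = aln$pnext,
             stringsAsFactors = FALSE)
}

#' Per-base coverage from alignment records
#'
#' @param records Alignment records ([read_sam()] / [alignment_records()]).
#' @param model A `numt_genome`.
#' @param min_mapq Drop reads below this MAPQ before piling up (default 0 =
#'   keep everything).
#' @return A named list of [S4Vectors::Rle] coverage vectors, one per contig
#'   in the model (nuclear chromosomes plus the mitochondrial contig).
#' @export
coverage_track <- function(records, model, min_mapq = 0) {
  stopifnot(inherits(model, "numt_genome"))
  seqs <- c(model$chrom_lengths,
            stats::setNames(model$mt_length, model$mt_name))
  records <- records[records$mapq >= min_mapq, , drop = FALSE]
  out <- lapply(names(seqs), function(ch) {
    sub <- records[records$chrom == ch, , drop = FALSE]
    if (!nrow(sub)) return(S4Vectors::Rle(0L, as.integer(seqs[[ch]])))
    ir <- IRanges::IRanges(sub$pos, width = sub$span)
    ir <- IRanges::restrict(ir, 1L, as.integer(seqs[[ch]]))
    IRanges::coverage(ir, width = as.integer(seqs[[ch]]))
  })
  names(out) <- names(seqs)
  out
}
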
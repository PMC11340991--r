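#' Numt insertion length model
#'
#' The default model is a two-component log-normal mixture (a short mode plus
#' a heavy long tail) truncated by rejection to `[min_length, mt_length - 1]`.
#' Its parameters were calibrated numerically so that large samples reproduce
#' the summary statistics reported for detected Numts: median ~73 bp,
#' mean ~1,169 bp, s.d. ~1,882 bp, minimum 22 bp.
#'
#' @param type `"mixture"` (calibrated default), `"lnorm"` (single
#'   log-normal), or `"fixed"` (degenerate at `length`).
#' @param weight Mixture weight of the short mode.
#' @param meanlog,sdlog Length-2 (mixture) or length-1 (`lnorm`) log-normal
#'   parameters.
#' @param length Fixed length for `type = "fixed"`.
#' @param min_length Lower truncation bound in bp.
#' @return An object of class `numt_length_model`.
#' @seealso [rnumt_length()]
#' @export
numt_length_model <- function(type = c("mixture", "lnorm", "fixed"),
                              weight = 0.6130,
                              meanlog = c(3.8473, 7.7447),
                              sdlog = c(0.4486, 0.6665),
                              length = 300, min_length = 22) {
  type <- match.arg(type)
  if (type == "mixture" && (length(meanlog) != 2L || length(sdlog) != 2L))
    stop("mixture model needs two meanlog/sdlog components")
  structure(list(type = type, weight = weight, meanlog = meanlog,
                 sdlog = sdlog, length = length, min_length = min_length),
            class = "numt_length_model")
}

#' Draw Numt lengths
#'
#' @param n Number of draws.
#' @param model A [numt_length_model()].
#' @param mt_length Mitochondrial genome length; lengths are truncated to be
#'   strictly smaller (an insertion of the whole circle is not representable).
#' @return Integer vector of lengths in bp.
#' @export
rnumt_length <- function(n, model = numt_length_model(), mt_length = 16569) {
  stopifnot(inherits(model, "numt_length_model"))
  if (n == 0L) return(integer(0))
  if (model$type == "fixed") {
    if (model$length >= mt_length)
      stop("fixed length must be smaller than 'mt_length'")
    return(rep(as.integer(model$length), n))
  }
  lo <- model$min_length
  hi <- mt_length - 1L
  if (lo > hi) stop("truncation bounds are empty: min_length >= mt_length")
  out <- integer(0)
  while (length(out) < n) {
    m <- max(2L * n, 100L)
    if (model$type == "mixture") {
      short <- stats::runif(m) < model$weight
      x <- numeric(m)
      x[short] <- stats::rlnorm(sum(short), model$meanlog[1], model$sdlog[1])
      x[!short] <- stats::rlnorm(sum(!short), model$meanlog[2], model$sdlog[2])
    } else {
      x <- stats::rlnorm(m, model$meanlog[1], model$sdlog[1])
    }
    x <- round(x)
    out <- c(out, as.integer(x[x >= lo & x <= hi]))
  }
  out[seq_len(n)]
}

#' Variant allele frequency model
#'
#' Log-normal model for the variant allele fraction (VAF) of somatic Numt
#' calls, clipped to (0, 1]. The `"cohort"` preset reproduces the low
#' mosaic VAFs of brain/blood tissue calls (median 4.4%); the
#' `"fibroblast"` preset reproduces the cultured-fibroblast calls
#' (median 9.1%).
#'
#' @param preset `"cohort"`, `"fibroblast"`, or `"custom"`.
#' @param meanlog,sdlog Log-normal parameters for `preset = "custom"`.
#' @return An object of class `numt_vaf_model`.
#' @export
vaf_model <- function(preset = c("cohort", "fibroblast", "custom"),
                      meanlog = NULL, sdlog = NULL) {
  preset <- match.arg(preset)
  par <- switch(preset,
    cohort     = list(meanlog = log(0.044), sdlog = 0.61),
    fibroblast = list(meanlog = log(0.091), sdlog = 0.75),
    custom     = list(meanlog = meanlog, sdlog = sdlog))
  if (is.null(par$meanlog) || is.null(par$sdlog))
    stop("custom VAF model needs 'meanlog' and 'sdlog'")
  structure(c(list(preset = preset), par), class = "numt_vaf_model")
}

#' Draw variant allele fractions
#' @param n Number of draws.
#' @param model A [vaf_model()].
#' @return Numeric vector in (0, 1].
#' @export
rvaf <- function(n, model = vaf_model("cohort")) {
  stopifnot(inherits(model, "numt_vaf_model"))
  pmin(stats::rlnorm(n, model$meanlog, model$sdlog), 1)
}

#' Sample Numt insertion events
#'
#' Places insertion points uniformly over the concatenated nuclear genome and
#' samples an mtDNA segment uniformly on the circular mitochondrial genome
#' with a length drawn from `length_model`. Segments may wrap the origin;
#' `mt_end < mt_start` encodes a wrapped segment. Uses the current R RNG.
#'
#' @param model A `numt_genome`.
#' @param length_model A [numt_length_model()].
#' @param n Number of events.
#' @param origin Origin label recycled over events (`"somatic"` or
#'   `"germline"`).
#' @return A `data.frame` with columns `chrom`, `pos` (1-based insertion
#'   point), `mt_start`, `mt_end` (1-based, inclusive, circular), `length`,
#'   `origin`.
#' @export
sample_numt_event <- function(model, length_model = numt_length_model(),
                              n = 1, origin = "somatic") {
  stopifnot(inherits(model, "numt_genome"))
  len <- rnumt_length(n, length_model, mt_length = model$mt_length)
  g <- ceiling(stats::runif(n) * nuclear_size(model))
  loc <- .global_to_pos(model, g)
  mt_start <- ceiling(stats::runif(n) * model$mt_length)
  mt_end <- ((mt_start + len - 2L) %% model$mt_length) + 1L
  data.frame(chrom = loc$chrom, pos = loc$pos,
             mt_start = as.integer(mt_start), mt_end = as.integer(mt_end),
             length = len, origin = rep_len(origin, n),
             stringsAsFactors = FALSE)
}

#' Length of a circular mtDNA segment
#'
#' Inverse of the `(mt_start, mt_end)` encoding used by [sample_numt_event()]:
#' inclusive 1-based endpoints on a circle of length `mt_length`, wrapping
#' when `mt_end < mt_start`.
#'
#' @param mt_start,mt_end 1-based inclusive endpoints.
#' @param mt_length Circle length in bp.
#' @return Segment length in bp.
#' @export
mt_segment_length <- function(mt_start, mt_end, mt_length = 16569) {
  ((mt_end - mt_start) %% mt_length) + 1L
}
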
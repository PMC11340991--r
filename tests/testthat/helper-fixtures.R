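# Small genomes and independent oracles shared across tests.

toy_genome <- function(lengths = c(chr1 = 5e7, chr2 = 5e7), ...) {
  make_genome_model(lengths, ...)
}

# Deterministic annotation fixture: one chromosome split by hand.
half_intron_genome <- function() {
  ann <- data.frame(
    chrom = "chr1",
    start = c(1, 401, 501),
    end = c(400, 500, 1000),
    category = c("intron", "CDS", "intron"))
  make_genome_model(c(chr1 = 2000), annotation = ann)
}

# Random (seeded) annotation over a small genome.
random_annotated_genome <- function(seed = 42, lengths = c(chr1 = 2e6,
                                                           chr2 = 1e6)) {
  set.seed(seed)
  make_genome_model(lengths,
                    annotation = simulate_annotation(lengths))
}

# Brute-force single-linkage clustering of 1-D positions: two positions are
# linked when within `window`; clusters are connected components.
brute_single_linkage <- function(chrom, pos, window) {
  n <- length(pos)
  lab <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) for (j in seq_len(n)) {
      if (chrom[i] == chrom[j] && abs(pos[i] - pos[j]) <= window &&
          lab[i] != lab[j]) {
        lab[lab == max(lab[i], lab[j])] <- min(lab[i], lab[j])
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  match(lab, unique(lab))
}

# Brute-force Benjamini-Hochberg step-up from the definition:
# q_(i) = min_{j >= i} min(1, m * p_(j) / j), reported in input order.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  ranked <- p[o]
  q <- numeric(m)
  for (i in seq_len(m))
    q[i] <- min(1, min(m * ranked[i:m] / (i:m)))
  out <- numeric(m)
  out[o] <- q
  out
}

# Alignment records for a hand-built anchor cluster whose mates map to the
# mtDNA contig; used to exercise caller thresholds precisely.
anchor_records <- function(pos, strand = "+", mapq = 60, span = 151,
                           chrom = "chr1", mate_pos = 5000,
                           read_length = 151) {
  n <- length(pos)
  data.frame(
    qname = sprintf("r%03d", seq_len(n)),
    flag = rep_len(ifelse(strand == "-", 81L, 65L), n),
    chrom = rep_len(chrom, n), pos = as.integer(pos),
    strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
    cigar = rep_len(paste0(span, "M"), n),
    read_length = rep_len(as.integer(read_length), n),
    span = rep_len(as.integer(span), n),
    mate_chrom = rep_len("chrM", n),
    mate_pos = rep_len(as.integer(mate_pos), n),
    stringsAsFactors = FALSE)
}

sorted_records <- function(df) df[order(df$chrom, df$pos), , drop = FALSE]
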
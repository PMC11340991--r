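# numtogenesis

Simulation, detection, and dynamics of nuclear mitochondrial DNA insertions
(Numts) from whole-genome sequencing.

Numts arise when fragments of the mitochondrial genome integrate into
nuclear chromosomes — an ongoing process ("numtogenesis") that operates not
only in the germline but somatically, in postmitotic brain tissue and in
cultured cells. Studying it from short-read WGS requires a chain of
specialized steps: detecting non-reference insertions from discordant read
pairs, separating somatic candidates from germline polymorphisms, testing
whether integration sites cluster in the genome or in genes, estimating
accumulation rates from repeated-measures designs, and relating the burden
to mitochondrial DNA copy number. This package implements that chain as
tested, reusable R functions, together with a seeded synthetic-data
generator with known ground truth, so that every stage can be validated by
parameter recovery.

It is intended for genomicists working on structural variation and
mito-nuclear biology, and for anyone who needs a transparent, testable
re-implementation of this analysis style on their own call sets.

## What it computes

**Detection.** Nuclear reads with mapping quality ≥ 10 whose mates map to
the mitochondrial contig are clustered by strand (single linkage within a
fragment-length window); forward and reverse clusters are paired into one
insertion event. A call records the breakpoint (innermost anchor edges,
with a confidence interval), the mtDNA segment (from mate positions, circle
wrap allowed), supporting pair count, Phred-scaled quality, local depth,
and the variant allele fraction

    VAF = supporting read pairs / read coverage .

`PASS` requires quality ≥ 50, support ≥ 4, depth ≥ 5×, and ≥ 150 bp of
anchored nuclear sequence (a screen against contaminant inserts).

**Somatic extraction.** Per-sample call sets are merged by transitive
closure of the "within ± 50 bp" relation; loci within ± 50 bp of a
population-reference Numt are removed as germline polymorphisms; loci whose
carriers all share one tissue (or cell line) are kept as somatic
candidates.

**Hotspots.** The genome is cut into 10-Mb bins; each observed site is
re-placed uniformly (50,000 shuffles in the full analysis) to form a
permutation null; per-bin enrichment is scored by the add-one empirical
p-value, Benjamini–Hochberg adjusted, with a Z-score
`(count − mean) / sd` across bins.

**Genic content.** Sites are classified CDS / UTR / intron / intergenic
(precedence CDS > UTR > intron) and each category's observed proportion is
tested against its genome base-pair fraction with a 2×2 Pearson chi-square
(Fisher's exact test when expected cells are small).

**Rates.** Longitudinal counts are fit by ordinary least squares,
`Y = β₀ + β₁X + ε` (X = days cultured), reported per 10 days with a
t-based 95% CI; slopes are compared between arms with the interaction
F-test (ANOVA) on median-normalized counts; cross-sectional contrasts use
Hedge's *g* and one-decimal fold-changes; age-at-death associations are fit
per cognitive stratum (NCI / MCI / AD from COGDX).

**mtDNA copy number.** `mtDNAcn = 2 × covMT / covautosomal` from median
per-base coverages, excluding MAPQ-0 reads and masked regions, with
batch-wise log/z standardization.

## Worked example

Plant one 1.5-kb insertion at 40% carrier fraction, sequence the region at
30× in silico, and call it back; then simulate the 12-line fibroblast
lifespan design and compare accumulation rates:

```r
library(numtogenesis)
genome <- make_genome_model(c(chr1 = 5e7, chr2 = 5e7))

set.seed(11)
event <- sample_numt_event(genome, numt_length_model("fixed", length = 1500))
event$vaf <- 0.4
reads <- simulate_read_evidence(genome, event, depth = 30)
detect_numts(reads, genome, sample_id = "demo")
#>   chrom      pos ci_lo ci_hi support depth qual filter
#> 1  chr1 27724981     0     0      24    31   99   PASS
event$pos   # planted at chr1:27724980

sim  <- simulate_longitudinal(genome, longitudinal_design_lifespan())
ctrl <- sim$series[sim$series$treatment == "none",  ]
surf <- sim$series[sim$series$treatment == "SURF1", ]
fit_rate(ctrl$day, ctrl$count)
#> rate_fit: slope 0.0825 /day (0.83 per 10 days, 95% CI 0.72-0.93),
#>           r2 = 0.914, p = 2.79e-14, n = 26
fit_rate(surf$day, surf$count)
#> rate_fit: slope 0.3853 /day (3.85 per 10 days, 95% CI 3.26-4.44),
#>           r2 = 0.923, p = 2.61e-10, n = 18
compare_slopes(ctrl, surf, "control", "SURF1")$p
#> 6.5e-17
fold_change(3.85, 0.83)
#> [1] 4.6
```

The caller recovers the planted breakpoint to 1 bp and the two fitted
slopes bracket their planted per-day rates (0.079 and 0.371); the slope
ANOVA rejects equality decisively. A full synthetic scenario — cohort
simulation, calling, merging, somatic extraction, hotspot testing, genic
annotation, rate fits, and copy-number estimation, with a JSON manifest of
outputs — runs via `run_pipeline(run_config(seed = 1), "out/")` or the
script in `inst/scripts/`.

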
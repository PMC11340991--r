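---
title: "Models and methods behind numtogenesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind numtogenesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette explains the statistical models, the synthetic-data
generator, and the numerical and design choices inside `numtogenesis` — the
things a user should understand before trusting results on their own data.

## The scientific setting

Numts are fragments of mitochondrial DNA integrated into nuclear
chromosomes. In short-read WGS they announce themselves through discordant
read pairs: one mate anchored to a nuclear chromosome near the insertion
breakpoint, the other mapping inside the mitochondrial genome. Somatic
Numts in bulk tissue are mosaic — carried by a small fraction of cells —
so their supporting evidence is thin (variant allele fractions of a few
percent), and the analysis leans heavily on cohort-level aggregation:
tissue-exclusive call sets, permutation tests for spatial enrichment,
genic-content contrasts, and longitudinal rate regressions in cultured
cells, where repeated sequencing of the same population lets the
accumulation rate be measured directly.

The package implements both the measurement machinery and a generator that
plants events with known truth, so every stage is validated by parameter
recovery rather than by eyeballing.

## The synthetic-data generator

### Insertion length

Observed Numt lengths are strongly right-skewed: a sharp short mode (tens
of bp) plus a heavy tail reaching kilobases. We model this as a
two-component log-normal mixture truncated by rejection to
`[22, mt_length − 1]` bp. The four log-normal parameters and the mixture
weight were calibrated numerically (Nelder–Mead on large-sample summary
statistics) so that draws reproduce median ≈ 73 bp, mean ≈ 1,169 bp and
s.d. ≈ 1,882 bp, the scale of reported non-reference Numt catalogs. The
defaults are frozen in `numt_length_model()`; `type = "fixed"` gives a
degenerate distribution for deterministic fixtures.

### mtDNA segments and placement

The mitochondrial genome is circular (16,569 bp in the human reference),
so a segment is stored as 1-based inclusive `(mt_start, mt_end)` with
`mt_end < mt_start` encoding wrap through the origin;
`mt_segment_length()` inverts the encoding. Insertion points are uniform
over the concatenated nuclear genome — each chromosome receives sites in
proportion to its length — which is also the null model of the hotspot
permutation test.

### Variant allele fraction

Call VAFs are modeled log-normally, clipped to (0, 1]. The `"cohort"`
preset (`meanlog = log 0.044`, `sdlog = 0.61`) reproduces the low mosaic
VAFs of bulk-tissue calls — median 4.4%, mean ≈ 5.3%, essentially all mass
below 35% — and the `"fibroblast"` preset (`meanlog = log 0.091`,
`sdlog = 0.75`) the higher cultured-cell values (median 9.1%). A single
log-normal cannot match the fibroblast median, mean and s.d.
simultaneously; we match the median exactly and accept a mean near 0.12,
since the medians are what downstream calibration checks use.

### Cohorts

`simulate_cohort()` builds a cross-sectional multi-tissue cohort:

* **Germline polymorphisms** come from a shared pool (default 60 loci);
  each sample carries each pool locus independently with probability
  `germline_mean / pool size` (default mean 7.4 per sample). Modeling
  germline events as *recurrent population polymorphisms* — rather than
  private per-individual variants — is what makes the downstream
  exclusivity filter meaningful: pool loci recur across tissues and are
  removed, exactly as germline Numts are in practice. A configurable
  fraction of the pool (default 10%) also appears in the returned
  population reference list, emulating published catalogs.
* **Somatic events** are tissue-specific, at per-tissue mean counts.
  Counts are Poisson by default; the ROSMAP-like preset
  (`cohort_design_rosmap()`) draws them gamma-mixed Poisson (negative
  binomial, size 1.05). The overdispersion is deliberate: real per-sample
  counts at means of 4.13 (DLPFC) vs 0.75 (cerebellum) separate with a
  standardized mean difference (Hedge's g) near 1, which pure Poisson
  noise cannot produce (it would give g ≈ 2.2). The preset's per-tissue
  means (DLPFC 4.13, cerebellum 0.75, PCC 1.71, AC 5.5, WB 3.52,
  PBMC 0.26) with germline mean 7.4 give an overall per-sample total
  near 10.4.
* **Ages at death** are Gaussian (mean 89, s.d. 7.63, truncated 59–108),
  chosen so that the <85 / 85–92 / ≥93 age groups receive roughly
  30/40/30% of samples. The somatic mean may depend linearly on age
  within each cognitive group (preset: −0.2 Numts/year in NCI, −0.1 in
  MCI, 0 in AD, floored at 0), planting the "more Numts, earlier death"
  signal that `age_association()` is tested against.

### Longitudinal series

`simulate_longitudinal()` plants a homogeneous Poisson arrival process:
unique events arrive at `rate_per_day` from day 0, persist once
integrated, and are re-detected at each collection independently with
probability `detection_prob` (default 1, so rate-recovery tests are
unconfounded by dropout; the probability is exposed because real
re-detection behavior at later passages is not known). All planted event
identities are distinct, mirroring the observation that every recovered
event in such experiments is unique — the signature that distinguishes
ongoing integration from clonal expansion of a few carrier cells.

`longitudinal_design_lifespan()` encodes the 12-series design of the
fibroblast aging experiment (3 healthy donors × untreated/Dex/Oligo plus
3 SURF1-mutant patients) with its published first/last collection days and
point counts; interior days are evenly spaced, consistent with the
~15-day average sampling interval of the protocol. Default per-day rates
are the published per-10-day rates ÷ 10 (control 0.079, Dex 0.107,
Oligo 0.215, SURF1 0.371).

### Read-pair evidence

`simulate_read_evidence()` works at the molecule level. Fragment starts
arrive at rate `depth / (2 × read length)` per bp; a fraction `vaf` of
molecules carries the insertion allele and lives on the ALT-haplotype
coordinate axis (reference with the insert spliced in). Each read of a
carrier molecule is mapped back to reference coordinates by a majority
rule: a read whose bases are mostly insert-derived is placed on the
mitochondrial contig at the corresponding segment offset; a
junction-straddling read that is mostly nuclear keeps its nuclear position
with the overhang soft-clipped in the CIGAR (or an insertion CIGAR when a
sub-read-length insert is fully contained). Non-carrier molecules emit
proper pairs; optional background chimeric pairs model stray
nuclear–mitochondrial artifacts. The fragment model is Gaussian
(mean 450 bp, s.d. 100 bp, truncated at twice the read length) — typical
for PCR-free libraries; read-length presets are 2 × 151 bp
(tissue cohorts) and 2 × 149 bp (fibroblast series).

The generator emits placements and CIGARs, not base sequences (`SEQ`/
`QUAL` are `*`): no sequencing-error or alignability model is implied.
Consequently, passing tests demonstrate correctness of the clustering,
breakpoint, filtering and rate logic — not robustness to mapping artifacts
in repetitive regions, which real data adds on top.

A structural consequence of paired-end evidence is worth stating: a mate
can only be assigned to the mitochondrial contig if the majority of its
bases are insert-derived, so inserts shorter than about half a read length
are invisible to this mechanism. Caller benchmarks therefore plant events
of ≥ 300 bp; the caller's sensitivity claims do not extend to
sub-read-length Numts (real pipelines recover some of these through
split-read or reference-Numt-mediated alignments, which are out of scope
here).

## The caller

`scan_discordant()` keeps nuclear anchors with MAPQ ≥ 10 whose mates map
to the mitochondrial contig and clusters them per chromosome and strand by
single linkage with a window of mean fragment length + 3 s.d. (750 bp
by default). `call_numts()` pairs forward with reverse clusters (greedy
nearest distance within the same window), then estimates:

* **Breakpoint** — forward cluster: rightmost anchor end + 1; reverse:
  leftmost anchor start; paired: the midpoint, with `CIPOS` spanning both
  one-sided estimates. Soft-clip-aware spans make the innermost edges
  land on the junction when straddling reads are present.
* **Quality** — `min(sum of supporting anchor MAPQs, 99)`, a Phred-scale
  score under which a 4-read MAPQ-60 cluster comfortably clears the ≥ 50
  threshold while low-MAPQ or thin clusters do not. (The ≥ 50 threshold is
  the established criterion; the score's computation is this package's
  choice, in line with common SV-caller practice.)
* **Local depth** — the median per-base coverage within ± 300 bp of the
  breakpoint ("around the insertion point" made concrete).
* **VAF** — supporting pairs divided by local depth by default; a
  `sample_mean` denominator is exposed because "overall read coverage in
  the sequenced genome" admits both readings, and neither is asserted as
  canonical.

Calls failing a threshold are *emitted* with filter flags
(`min_support`, `min_depth`, `min_qual`, `one_sided`, `anchor_lt150`)
rather than dropped, so filtering is auditable and monotone: lowering any
threshold never removes a PASS call. Split-read refinement is not
implemented; the confidence interval carries the residual breakpoint
uncertainty (typically a few tens of bp).

## Merging, population filtering, exclusivity

Merging is transitive (single-linkage) closure of "within ± 50 bp on the
same chromosome": chains can exceed 50 bp end-to-end, which is the
standard behavior of SV merging modules and is accepted here.
Population filtering matches the representative breakpoint (median of
members) against reference entries by distance only — population catalogs
publish genomic positions, not mtDNA segments. Exclusivity keeps loci
whose carriers all share one group label. A locus recurring in many
samples of *one* tissue is retained by default (annotated with its carrier
count), because treating such recurrence as germline is a judgment call;
`max_carriers` enables the stricter reading.

## Hotspot testing

Bins are chromosome-bounded, 10 Mb nominal width, terminal bins shorter
(coordinates 0-based half-open, BED-style). The null re-places every
observed site uniformly over the concatenated nuclear genome; per-bin
p-values use the add-one estimator `p = (1 + #{null ≥ obs}) / (n + 1)`,
which is never zero and is super-uniform under the null — the calibration
test checks exactly that direction (one-sided Kolmogorov–Smirnov), since
the estimator's discreteness pushes mass only the conservative way.
Benjamini–Hochberg adjustment is applied within each stratified run, and a
bin is a hotspot when `q < 0.05` (strict). Z-scores use the sample
standard deviation across bins. The ambiguity mask is ignored during
shuffling by default — the documented analysis gives no indication masked
regions were excluded from placement — with `respect_mask = TRUE`
available. Sites are points (breakpoints), not intervals; length-weighted
shuffling and local background corrections (GC, mappability) are
non-goals.

## Genic content

Overlapping transcript features resolve by precedence
CDS > UTR > intron > intergenic at model-build time, producing a disjoint
tiling, so classification is a single interval lookup and is invariant to
transcript ordering. Expected counts are base-pair fractions × total
sites. Each category is tested as a 2×2 table (inside vs rest; observed vs
expected) with Pearson chi-square without continuity correction, switching
to Fisher's exact test when any expected cell is below 5 — the classical
small-sample rule, made explicit. `simulate_annotation()` draws gene
structures whose genome-wide fractions approximate the human annotation
(intergenic ≈ 63.9%, intron ≈ 34.9%, CDS + UTR ≈ 1.2%); whole inserted
intervals are not classified, only insertion points.

## Rates and effect sizes

Accumulation rates are ordinary least squares on raw counts pooled across
the donors of an arm, reported per 10 days with a t-based 95% CI
(n − 2 df). Median normalization (`normalize_by_group_median()`) is
applied only when *comparing* slopes across arms — it rescales each arm by
its own typical count, and therefore changes slopes; using it for the
reported rates would destroy their per-day units. A zero group median
falls back to a divisor of 1 with a warning rather than producing
infinities. `compare_slopes()` fits the pooled interaction model
`Y ~ X * group` and reports the interaction F-test, which equals both the
nested-model ANOVA and the square of the two-sample slope t-statistic.

Hedge's g uses the pooled s.d. and the small-sample correction
`J = 1 − 3/(4(n_A + n_B) − 9)`; fold-changes are rounded half-even to one
decimal, matching how such ratios are conventionally printed. Cognitive
groups map from COGDX as 1 → NCI, 2–3 → MCI, 4–5 → AD; age groups are
boundary-inclusive at 85 and 93. Mixed-effects modeling and
multiple-testing across strata are deliberately out of scope: the
reference analyses report raw per-stratum r² and p.

One caveat on longitudinal inference: counts along one series are a
cumulative process, so residuals are autocorrelated and the OLS standard
error understates replicate-to-replicate slope variability. The package's
recovery tests therefore assess the *mean* fitted slope across hundreds of
simulated replicates (where OLS is unbiased), not single-series CIs.

## mtDNA copy number

`mtDNAcn = 2 × covMT / covautosomal` from median per-base coverages;
MAPQ-0 reads are excluded before pile-up and masked nuclear positions are
excluded from the autosomal median. The estimate is scale-invariant in
sequencing depth. The median is the default center (mean, median and mode
give near-identical estimates at WGS depths, so nothing hinges on it).

Batch standardization: the documented order of operations is
"z-standardize within batch, then logarithmize", but a z-score is signed,
so its logarithm is undefined for half the data. The default here applies
`log10` *first* and then standardizes within batch — preserving the intent
(batch-normalized, variance-stabilized, approximately normal values) while
staying mathematically well defined. The literal order is kept as
`order = "z_first"`, which shifts each batch's z-scores by
`−min + 1` before the log; both orders are monotone within batch.

## Pipeline, seeding, problem sizes

`run_pipeline()` chains the stages on a synthetic scenario, writing each
stage's artifacts plus a JSON manifest of parameters and MD5 checksums;
a rerun with the same configuration is checksum-identical. Every stage
reseeds deterministically from the configured seed, so stage subsets are
reproducible too. All generator and analysis functions consume R's RNG:
`set.seed()` (or the `--seed` flags of the scripts) controls everything.

The shipped test and demo sizes are chosen for fast, well-powered
validation: toy genomes of 1–2 chromosomes × 50 Mb for caller and
permutation tests; the full 1,187-sample cohort preset where cohort-level
means are checked; 500 replicates for rate recovery; 1,000 permutations ×
20 seeds for null calibration of the hotspot engine (the full analysis
uses 50,000 permutations — the engine is the same, only `n_iter`
changes).

## Known limitations

* No base-level sequence simulation: FASTQ, sequencing error, mappability
  and GC structure are absent, so tests validate logic, not alignment
  robustness.
* Sub-read-length insertions are invisible to pure discordant-pair
  evidence (see above); split-read refinement is not implemented.
* Reference-Numt-mediated evidence (mates hitting annotated reference
  Numts rather than the mitochondrial contig) is out of scope.
* The caller's VAF is the supporting-read ratio of the published
  definition; on deeply-covered junctions it is a different quantity from
  the molecular carrier fraction and should not be read as one.
* Hotspot shuffling is genome-uniform; if your question requires
  mappability- or GC-matched nulls, this engine will not provide them.
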
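---
title: "Methods: SNP discovery in reference-poor polyploids with rrsnp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: SNP discovery in reference-poor polyploids with rrsnp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(rrsnp)
```

This vignette documents the models and procedures behind `rrsnp`, the
parameters that matter, the simulator that defines the package's test
conditions, and the design decisions taken where the underlying method
descriptions left room. It states no measurement that the test suite and
`scripts/acceptance.R` do not themselves compute.

## 1. The analysis model

The pipeline targets species with *no genome assembly* and *mixed
polyploidy*. Its chain of custody for a variant call is:

EST reads → cleaned ESTs → unigene clusters → consensus "gene-space"
reference → QC'd restriction-anchored short reads → banded
Smith–Waterman alignments → per-column pileups → two-stage dosage-aware
variant calls → dominant-marker genotypes → PCA / diversity summaries.

Two assumptions shape everything downstream:

* **Cut-site anchoring.** Libraries are made with the
  methylation-sensitive enzyme HpaII (recognition CCGG, cut C^CGG). Every
  legitimate read therefore starts with the 5' `CGG` overhang, and reads
  stack on the two ends of each unmethylated cut site rather than being
  spread uniformly. QC exploits this (the prefix check); the simulator
  reproduces it.
* **Allele dosage.** An individual of ploidy *p* carries an allele on
  *k* ∈ {0, …, p} copies; read counts at a heterozygous site concentrate
  around (p−k):k. An octoploid single-dose site is expected at 7:1, which
  motivates the inclusive 1:7–7:1 ratio band in the caller: wider
  imbalances are treated as sequencing/assembly error, not genotype.

## 2. Stage parameters

| stage | parameter (unit) | default | rationale |
|---|---|---|---|
| QC | `expected_prefix` | `CGG` | HpaII overhang; reads without it are broken molecules |
| QC | `max_homopolymer` (bp) | 16 | runs *larger than* 16 bp discard the read (boundary inclusive-pass) |
| QC | `min_qual` (phred) | 10 | 3' trim until every remaining base ≥ 10 |
| QC | `min_len_after_trim` (bp) | 12 | shorter reads are uninformative for a word-12 index |
| index | `word_size` (bp) | 12 | never stated by the original tool; chosen equal to the shift and flagged as a guess |
| index | `shift_size` (bp) | 12 | supported range 11–16; smaller is slower but more sensitive |
| align | `max_mismatches` | 2 | absolute cap (reads average ~25 bp after trimming) |
| align | `max_gap_len` (bp) | 3 | total gapped bases; each event 1–3 bp |
| align | `band_halfwidth` (bp) | = `max_gap_len` | narrower bands would make permitted gaps unreachable |
| align | `min_read_len` (bp) | 12 | minimum aligned bases |
| align | `max_clip` (bp) | 6 | maximum soft-clipped read bases (see §4) |
| call | `d` (reads) | 3 | alternate reads required within one library |
| call | `l` (reads) | 3 | alternate reads required pooled across libraries |
| call | `max_ratio` | 7 | inclusive ref:alt band, octoploid dosage rationale |
| call | `min_base_qual` (phred) | 20 | applied to every counted base, reference and alternate alike |
| call | `min_depth_at_site` (reads) | 3 | total filtered depth in the unit being tested |
| genotype | `min_depth` (reads) | 4 | ≥4+0 homozygote, ≥4+≥4 heterozygote, else missing |
| EST clean | window / threshold | 11 bp / phred 15 | sliding-window mean quality |
| EST clean | insertless | >200 bp 5' vector or <100 bp non-vector | clone carries no usable insert |
| EST cluster | k-mer / seed / identity | 16 / 32 bp / 0.98 | overlap clustering stringency |

Alignment scoring (match +1, mismatch −1, gap of length *k* costs
2 + *k*) is the package's own choice — the caps above, which *are*
method-specified, remain the binding constraints; the scheme is exposed in
`align_params()` and matched exactly by the independent oracle used in the
tests (`Biostrings::pairwiseAlignment`, gapOpening 2 / gapExtension 1).

## 3. The two-stage caller

Stage 1 (*per-library*) asks whether any single library shows ≥ `d`
alternate reads with an in-band ratio and sufficient depth — this is what
detects heterozygosity *within* a polyploid individual. Stage 2
(*pooled*) repeats the identical test on summed counts with threshold
`l`, catching alleles spread thinly across libraries (e.g. one read in
each of three libraries). The published description never states how the
two flags combine; its "two stages … followed by … combined reads"
narrative reads most naturally as a union, and `rrsnp` implements exactly
that, labelling each record `per_library`, `pooled` or `both`. The union
property is asserted in the test suite.

Within a stage the ratio band is applied to the unit being tested (the
single library in stage 1, the pool in stage 2), because the 1:7
justification is per-individual dosage. The boundary is inclusive — a
site at exactly 7:1 is called. A consequence worth knowing: a library
with *only* alternate reads (0:n) fails the band in stage 1; such sites
are recovered by the pooled stage when other libraries contribute
reference reads.

Only the top alternate allele per column is tested (ties broken by count,
then summed base quality, then lexicographically); further alleles are
tallied in `n_other_alleles` but not called, since multi-allelic handling
was unspecified. Indels (1–3 bp) run through the same machinery as
alleles of the anchoring column, left-normalised, with one observation
per read per column (a read's indel observation replaces its base
observation at the anchor).

## 4. Numerical and algorithmic choices

* **Banded DP.** The aligner is a banded Gotoh local alignment in C++;
  with the band at least as wide as both sequences it equals unbanded
  Smith–Waterman, a property the acceptance suite checks against an
  independent full-DP implementation on 500 random pairs.
* **End extension at mapping time.** Pure local alignment never ends on a
  mismatch, so a variant on a read's terminal base would be soft-clipped
  and systematically invisible. `map_library()` therefore extends the
  optimal local alignment gaplessly to the read ends, counting the extra
  mismatches against the 2-mismatch cap. `banded_sw()` keeps pure
  Smith–Waterman semantics (`extend_ends = FALSE`) so the equivalence
  property above is tested against an unmodified oracle.
* **Clip cap.** A chance 12-mer word hit can anchor a short (12–15 bp)
  local alignment of a read whose true locus is absent from the
  reference; because seeds only exist at indexed offsets, such fragments
  pile up at word-sampled positions and fabricate deep variant columns.
  `max_clip = 6` requires near-full-length alignment and eliminates the
  artefact; reads overhanging a reference boundary by more than 6 bp are
  reported unmapped, consistent with whole-read mapping.
* **Multi-hit penalty.** Score ties are broken by
  Σ read_qual × end_weight over mismatches, end_weight 0.5 within 3 bp of
  either read end — an operationalisation of "quality scores at the
  mismatch positions and the location of the mismatches" (the original
  weighting is unpublished). The formula is isolated in
  `resolve_multihits()`. Remaining ties discard the read; there is no
  randomised tie-breaking anywhere in the package.
* **3' trimming.** The published descriptions conflict ("trim from the 3'
  end until a threshold is reached" vs "a minimum … for the remaining
  sequence"). Default: cut at the first base below `min_qual`, the unique
  longest prefix satisfying the minimum-over-remaining reading; the
  strip-trailing-run alternative is available as `trim_mode = "tail_run"`.
* **Quality-window splitting (ESTs).** Every base covered by an 11-base
  window whose mean quality is below 15 is flagged; fragments are the
  unflagged runs and the longest is kept. Mean (not minimum) follows the
  stated "average quality score in the window".
* **Low complexity** is undefined in the source material; implemented as
  3-mer Shannon entropy in 64-base tiles, flagging tiles below 1.5 bits,
  with the read discarded when flagged bases exceed 50%.
* **Identity-sweep selection.** The sweep picks the identity immediately
  below the largest *relative* increase in consensus count between
  adjacent grid points (ties → earliest; counts that never increase →
  "no jump", configured default). Relative increase was chosen because
  the grid is short and absolute counts scale with input size.
* **Degenerate inputs.** Empty FASTQ → empty stream; empty variant table
  → header-only VCF; all-missing genotype matrix → warning and empty
  matrix; zero-variance PCA input → error; reference records shorter than
  the word size → warning, no words.

## 5. What the simulator emulates — and what it does not

`sim_config()` defaults define the package's study conditions: 500 kb
genome, genic fraction 0.5 (the genic intervals *are* the mapping
reference, mimicking a transcriptome scaffold), six libraries (three
tetraploid, three octoploid individuals), θ = 0.005 with 5% short indels,
two CCGG sites/kb with 30% methylated, 35 bp reads from both ends of each
unmethylated site, and a two-tier quality model (phred 35 at 0.1% error,
phred 15 at 3%, low-tier weight 3.5% — ≈0.2% average error) chosen so the
quality-20 filter separates the tiers sharply.

Per-site coverage defaults to 25 reads per fragment end per library.
This is a deliberate calibration to the genotype rule: declaring a
heterozygote needs ≥ 4 reads of *each* allele, and a single-dose
octoploid site yields the minor allele in only 1 read of 8 — at a few
dozen reads per site the rule gets a fair look at such alleles, while at
shallow depth almost every extreme-dosage heterozygote is either missing
or indistinguishable from a homozygote.

Emulated: cut-site anchoring with correct overhang on both strands,
methylation sensitivity, per-read binomial sampling of haplotype copies
(what makes the ratio filter exercisable), population allele frequencies
with per-individual binomial dosage, quality-dependent substitution
error, EST clone pairs with insertless/quality/poly-A/low-complexity
defects, and gene families with controlled paralog/allele divergence.

Not emulated — so passing tests say nothing about: PCR duplicates,
indel *sequencing* errors (true indels are planted as variants;
sequencing errors are substitutions only), transposon landscapes and
genuine repeat families, cut-site polymorphism (variants never fall in
the CCGG motif), linkage/recombination structure (alternate alleles sit
on copies 1..dosage, so within-individual haplotypes are maximally
correlated), and contamination. Real data will also carry
quality-miscalibration that the two-tier model does not represent.

One idealisation deserves emphasis: the "deep uniform coverage" mode of
`simulate_site_counts(sampling = "balanced")` gives every haplotype copy
equal depth, so a dosage-1/8 site sits exactly on the inclusive 7:1
boundary and always passes. Under binomial copy sampling the observed
ratio straddles that boundary and roughly half of deep replicates fall
outside — an inherent property of placing the filter bound exactly at the
single-dose expectation, not a depth issue. The dosage-filter acceptance
property therefore uses balanced sampling as the idealised deep-coverage
limit; the binomial mode is the default everywhere else.

## 6. Scope of the bundled evaluation

The acceptance suite runs the full pipeline at the default conditions
above (a few hundred thousand reads; about two minutes on one CPU) and
scores calls against ground truth restricted to *eligible* sites — truth
sites whose simulated high-quality, fully-genic read counts satisfy the
caller's own conjunction. Recall is reported against eligible sites,
precision against all calls, and genotype accuracy on complete-case
columns matched to truth. The EST→reference stage is exercised separately
(identity sweep on simulated gene families; cleaning/clustering unit
tests) rather than inside the recovery run, keeping the recovery
measurement attributable to QC → mapping → calling → genotyping alone.

## 7. Known limitations

* The genotype rule is dominant-marker by construction: extreme-dosage
  heterozygotes with no sampled minor-allele read are called homozygous;
  complete-case filtering enriches for exactly those cells. This is a
  property of the rule, not of the implementation.
* Only the top alternate allele per site is called; genuinely
  multi-allelic sites are under-reported (counted in
  `n_other_alleles`).
* The consensus builder is a star alignment with majority vote — adequate
  for clustering-quality references, not a general assembler; exact
  contigs of a dedicated assembler are out of scope.
* Alignments are reported in a package-specific table (and debug TSV),
  not SAM/BAM; spliced alignment and paired-end logic are out of scope.
* EST vector *screening* is upstream: `clean_est()` consumes a supplied
  vector mask and an optional contaminant list; reproducing any
  particular screening database is not attempted.
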
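---
title: "Methods: variant landscapes, synthetic cohorts and RNA-editing detection"
author: "variscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variant landscapes, synthetic cohorts and RNA-editing detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(variscape)
```

## Scope and model

`variscape` implements the downstream half of a two-individual whole-genome
resequencing analysis: it starts from called variants (VCF), gene models
(GFF3), a reference (FASTA) and per-site allele pileups, and produces the
filtered, annotated variant landscape plus RNA-editing calls. Read mapping,
duplicate marking, base recalibration, variant calling and de novo assembly
are upstream of the package and out of scope; their published summary
tallies are accepted as inputs to the arithmetic helpers
(`mapping_summary()`, `retention_percent()`, `coverage_estimate()`).

The underlying genetic model is a diploid individual compared to a haploid
reference: every called locus falls into genotype class 0/1 (heterozygous,
one allele equal to the reference), 1/1 (homozygous non-reference) or 1/2
(heterozygous with two non-reference alleles). Multi-allelic records are
deliberately kept unsplit because 1/2 is a first-class category in the
zygosity summaries; the heterozygous count is defined throughout as
0/1 + 1/2 and the homozygous denominator as non-reference 1/1 only.

## Hard filtration

`apply_hard_filters()` evaluates six named filters on standard site
metrics. Two interpretive choices deserve note:

* the low-coverage bound is read literally as *fail when `DP <= 20`*; the
  bound is configurable because pileup-level analyses elsewhere in the
  package use 5x minima;
* the mapping-quality filter is treated as a rank-sum-style metric
  (negative values are meaningful) read from a configurable INFO key.
  Conventional filter option lists sometimes repeat this filter; it is
  implemented once.

A filter whose metric is absent is recorded as not evaluated rather than
failed; `strict = TRUE` turns missing metrics into errors. Filtration is
idempotent and order-independent because every filter is evaluated on the
original record.

## Context and impact annotation

`assign_context()` gives each variant exactly one label under the
precedence `cds > utr5/utr3 > intron > upstream > downstream >
intergenic`, the "most relevant context" doctrine used by standard effect
annotators. Upstream/downstream are strand-aware 5 kbp windows (the
conventional promoter-scale default; configurable). When two genes offer
the same context class, the tie goes to the smaller gene span, then the
lexicographically smaller gene id — an arbitrary but deterministic rule.

Coding SNPs are classified by rebuilding the affected codon on the coding
strand (reverse complement for minus-strand genes) and translating old and
new codons with the standard nuclear code — the only code supported. A
start codon that stops being ATG is `start_lost` even when the replacement
is an alternative initiator (TTG/CTG); the unit tests' independent oracle
translates whole proteins with initiator special-casing disabled for the
same reason.

Coding indels are first left-normalized (VCF parsimony: shared suffix then
shared prefix stripped, keeping one anchor base). A net length change not
divisible by 3 is a `frameshift`. In-frame deletions whose removed bases
start on a codon boundary are `codon_deletion`, otherwise
`codon_change_plus_deletion`; in-frame insertions at a codon boundary are
`codon_insertion`, otherwise `codon_change_plus_insertion`. The
classification is positional — it does not attempt to detect the rare
coincidence where a mid-codon in-frame event happens to reproduce a pure
codon insertion at the protein level.

## Landscape statistics

Quartiles for Tukey's fences use linear interpolation (`stats::quantile`
type 7, the R default); the convention is pluggable via `qtype` and the
test suite checks agreement with an independent sort-based implementation.
Values *strictly* outside the fences are flagged. Ti/Tv is reported as an
undefined sentinel (`NA`) when a group has no transversions rather than as
infinity, and multi-allelic SNPs contribute one substitution per alternate
allele. Per-chromosome frequencies exclude virtual chromosomes
("Un", "*_random") by configurable name patterns, since those bins collect
unplaced sequence and would distort per-bp rates. Context-percentage
denominators are computed from the gene models as the union bp of each
context class under the same precedence used for labelling, so the
percentages are internally consistent (`percent x bp / 100` re-sums to the
event count) — they are not calibrated to any external feature-size
convention.

## Sequencing and assembly metrics

Fold coverage uses the ceiling, `ceil(reads x read length / genome
size)`: a partial fold requires the corresponding sequencing effort, and
the ceiling is the convention under which the standard 125 bp paired-end
arithmetic is self-consistent across retained-read and assembly-read
counts. N50 is the length of the contig at which the descending cumulative
length first reaches half the assembly. GC percentage counts C+G over the
*total* length, so ambiguous bases dilute GC rather than being excluded.

## RNA-editing detection

The caller operationalizes "transcript nucleotide unsupported by the
genome" as: after discarding alleles below 10% read support (inclusive),
an RNA-retained base absent from the DNA allele profile. Both the 10%
support bound and the 90% homozygosity bound are boundary-inclusive and
configurable; the same support filter is applied to the DNA and RNA side.
Because sub-threshold genomic support (a base present in, say, 8% of
genome reads) can create false positives, `strict = TRUE` additionally
requires zero genomic reads of the edited base. The gate ahead of the
comparison requires simultaneous 5x DNA and RNA coverage, expression
(RPKM >= 1) in all six RNA samples, and no indel evidence; every excluded
site carries a machine-readable reason, and passes plus failures always
sum to the input sites. Editing is called per RNA sample; edits are
reported in DNA alphabet (T-to-A, not U-to-A). A separate
`rna_variant_prefilter()` reproduces the upstream transcriptome-variant
screen (sequence-end proximity, reference ambiguity, flanking copy number,
allele quality and support, 15% minimum variant frequency, 4-read minimum
coverage); the copy-number metric is accepted as supplied metadata since
its flanking-window definition is not standardized.

## The synthetic cohort

`sim_config()` fixes the study conditions the package is validated under;
the generator is first-class, tested code, not a fixture.

* **Genome and genes.** Random uniform-composition chromosomes (three, 100
  to 120 kb, at the defaults) with 9 protein-coding genes: ATG start,
  in-frame stop, no internal stops, CDS length a multiple of 3, 1 to 3
  exons, optional UTRs, and at least 12 kbp between genes so adjacent 5 kbp
  context windows need not overlap.
* **Variants.** The union of SNP (0.012/bp) and indel (0.0024/bp) positions
  is drawn uniformly without replacement, so SNPs and indels never collide.
  The rates are chosen to match a wild-versus-reference grapevine
  comparison at desk scale: roughly 6 million SNPs and 1.2 million indels
  per individual on a 486 Mbp genome. Each union variant is planted in both
  individuals with probability `shared_fraction` (default 0.5, matching
  the observation that the two individuals shared about half their
  variants); shared variants carry identical alleles *and* genotype class
  so that their (chrom, pos, ref, alt) identity is the same in both call
  sets — a deliberate simplification that makes sharing exactly
  recoverable from set arithmetic.
* **Genotype classes.** Heterozygous with probability `het_fraction`
  (default 0.65, i.e. het/hom near 1.8); heterozygous records are 1/2 with
  probability 5/65, reproducing a 60:35:5 0/1:1/1:1/2 mix. Indels are
  never 1/2 (a simplification; multi-allelic indel loci are rare and add
  nothing to the tested properties).
* **Ti/Tv.** The transition probability per drawn allele is not simply
  `R/(1+R)`: 1/2 records draw a second non-reference allele, and when the
  first alternate is the transition partner the second is forced to be a
  transversion. The generator therefore solves
  `p + q(1-p)p = (1+q) R/(1+R)` for `p` (with `q` the expected 1/2
  fraction) so that the *allele-level* expected Ti/Tv equals the target
  `R` (default 2.0, typical of plant genome-wide SNP sets).
* **Depths and editing.** Site depths are Poisson around the configured
  means (DNA 40x, RNA 60x) — the zero-overdispersion corner of the
  gamma-Poisson family, adequate because no tested property depends on
  depth variance. Editing events are planted only at exonic transcript
  offsets, never on top of a planted DNA variant, one RNA sample per
  auto-placed event; two-variant events use a 0.4 edited fraction
  (binomially sampled per site) and full edits 1.0. Expressed genes draw
  RPKM targets in [5, 50]; one designated gene stays an order of magnitude
  below the RPKM floor to exercise the expression gate.
* **Determinism.** All draws derive from `config$seed`; identical configs
  reproduce the cohort byte for byte (FASTA, GFF3, TSVs, truth JSON; VCFs
  are bgzip-compressed, so determinism is asserted on parsed content).

What the generator does *not* emulate: sequencing error, read-level data
(no FASTQ/BAM), alignment artifacts, overdispersed or GC-biased coverage,
linkage and recombination structure, somatic mosaicism, multi-transcript
isoforms, and reference ambiguity (no N bases). Passing recovery tests
therefore demonstrate the correctness of the statistical machinery under
clean planted truth, not robustness to real-data noise — the hard-filter
and prefilter stages that would absorb such noise are tested separately on
constructed records.

## Problem sizes and test design

The validation suite runs three cohort scales, chosen to keep the full
suite around a minute while leaving sampling error well below the tested
tolerances: a 160 kb / 6-gene cohort shared across unit tests; a 1 Mbp
cohort with ~12,000 union variants for 3-standard-error recovery of the
planted Ti/Tv, heterozygous fraction and shared fraction; and a 300 kb /
8-gene cohort with 200 planted editing sites on which the caller must
reach sensitivity 1.0 with zero false calls (at 0.4 edited fraction and
60x RNA depth, the probability that a planted event falls under the 10%
support bound is negligible, of order 1e-8 per site). Codon-impact logic
is validated against a brute-force oracle that re-translates the entire
protein before and after each of 500 random coding SNPs, and N50 and
Tukey-fence implementations against independent brute-force oracles on
1,000 random inputs each.

## Known limitations

* One transcript per gene; splice-site effect classes are not assigned.
* Only the standard nuclear genetic code is supported.
* Indel impact is positional, as described above, and indels spanning a
  CDS boundary are conservatively treated as frameshifts.
* The editing caller assumes pileups are already aligned to the same
  reference coordinates for DNA and RNA; it performs no realignment.
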
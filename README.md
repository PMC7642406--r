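# variscape

Downstream analysis of diploid genome resequencing against a reference, for
study designs that compare a small number of individuals — typically two —
at the whole-genome level and follow up with matched RNA-seq. The package
covers the analysis stages that sit *after* read mapping and variant
calling: hard filtration of raw calls, gene-context and protein-impact
annotation, genome-landscape statistics, sequencing/assembly summary
metrics, and detection of RNA editing from matched DNA-seq and RNA-seq
allele pileups. A deterministic synthetic-cohort generator with planted
ground truth makes every stage testable end to end without any external
data.

## What it computes

**Variant hard filters.** Named filters applied to standard site metrics,
with SNP/indel-specific bounds: depth `DP <= 20` (LowCovFilter), quality by
depth `QD < 2.0`, mapping-quality rank-sum `< -12.5`, Fisher strand bias
`FS > 60` (`> 200` for indels), haplotype score `> 13`, read-position
rank-sum `< -8` (`< -20` for indels). Every failed filter is recorded in
the FILTER field; all bounds are configurable.

**Effect annotation.** Each variant receives exactly one genomic context
with the precedence `CDS > UTR > intron > upstream > downstream >
intergenic` (upstream/downstream are strand-aware 5 kbp windows; a site
between two genes is labelled by the more relevant context, e.g. upstream
of the next gene rather than downstream of the previous one). Coding SNPs
are classified by rebuilding the affected codon on the coding strand and
translating with the standard nuclear code (synonymous, non-synonymous,
stop gained/lost, start lost); coding indels by frame arithmetic and codon
alignment (frameshift when the net length change is not a multiple of 3;
otherwise codon insertion/deletion, plus "codon change +
insertion/deletion" when the event straddles a codon boundary).

**Landscape statistics.** Transition/transversion ratio
`Ti/Tv = #(A<->G, C<->T) / #(other substitutions)` per context group
(uniform-substitution null: 0.5); per-chromosome event frequencies
(events / chromosome bp) with Tukey's outlier fences
`[Q1 - k*IQR, Q3 + k*IQR]`, k = 1.5, excluding virtual ("Un"/"*_random")
chromosomes; shared/exclusive variant sets keyed by (chrom, pos, ref, alt);
zygosity tallies with the heterozygous over non-reference-homozygous ratio
`het/nonref-hom = (#0/1 + #1/2) / #1/1`; percent of each context class
affected; and binned densities along chromosomes.

**Sequencing and assembly metrics.** Mapping-category percentages of total
mapped reads, read-retention percentages, expected fold coverage
`ceil(reads x read length / genome size)`, minimum-length contig
filtering, N50 and GC percentage.

**RNA editing.** A site enters the comparison only when DNA and RNA
coverage are simultaneously >= 5x, the host gene is expressed (RPKM >= 1,
`RPKM = 1e9 * reads / (exon bp x library size)`) in all six RNA samples
(two individuals x three developmental stages), and the site shows no
indel evidence. Alleles below 10% read support are discarded as errors; a
locus is homozygous when its dominant allele reaches 90% (both bounds
inclusive). An RNA-retained base absent from the DNA allele profile is an
editing call: a *two-variant* event when edited and unedited transcripts
co-occur, a *full edit* when only the edited form is seen. Calls are
annotated with context and codon impact and summarized per gene and per
genomic window (e.g. a sex-determining region).

## Worked example

```r
library(variscape)

cfg <- sim_config(seed = 11)                  # 340 kb genome, 9 genes
sim <- run_simulate(cfg, "demo")              # FASTA/GFF3/VCF/pileups/truth
land <- run_landscape(sim$individuals$WF, sim$individuals$WM, sim$genome_obj)

land$venn_snp
#> $shared  [1] 2034
#> $only_a  [1] 1029
#> $only_b  [1] 1017
```

About half of the SNPs are shared between the two simulated individuals,
the planted `shared_fraction` of 0.5. Zygosity tallies recover the planted
heterozygous fraction (0.65, i.e. het/hom near 1.9):

```r
z <- land$zygosity
agg <- aggregate(cbind(het, hom_alt) ~ individual + kind, z, sum)
agg$ratio <- round(agg$het / agg$hom_alt, 2)
#>  individual  kind  het hom_alt ratio
#>          WF indel  381     225  1.69
#>          WM indel  373     225  1.66
#>          WF   snp 2035    1028  1.98
#>          WM   snp 2010    1041  1.93
```

The editing caller recovers exactly the planted events and locates them in
the gene body:

```r
ed <- run_editing(sim$pileups, sim$genome_obj)
ed$summary$per_gene
#>    gene sample events cds_events non_cds_events
#>  gene08   WM_D      1          1              0
#>  gene03   WF_H      1          1              0
#>  gene08   WF_D      1          1              0
#>  gene05   WM_D      2          0              2
#>  ...
```

Published summary tables can be fed straight into the metric helpers:

```r
run_metrics(mapping  = c(unique = 187424438, non_unique = 22198252,
                         singletons = 1782319, cross_contigs = 20897087),
            retention = data.frame(label = "WF", reads_kept = 216895404,
                                   reads_total = 236749964),
            coverage  = data.frame(label = "WF", n_reads = 224542530))
#> $mapping      unique 89.41% | non-unique 10.59% | singletons 0.85% | ...
#> $retention    WF 91.6
#> $coverage     WF 58
```

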
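Package: variscape
Title: Variant Landscapes and RNA Editing in Two-Individual Resequencing Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of diploid genome resequencing against a
    reference: hard filtration of called variants, gene-context and
    protein-impact annotation, genome-landscape summaries (transition/
    transversion ratios by context, per-chromosome event frequencies with
    Tukey outlier fences, shared/exclusive variant sets, zygosity tallies
    and heterozygous over non-reference-homozygous ratios), sequencing and
    de novo assembly summary metrics (mapping-category percentages, read
    retention, fold coverage, N50, GC content), and detection of RNA
    editing from matched DNA-seq and RNA-seq allele pileups under a
    conservative filter cascade with RPKM expression gating. Includes a
    deterministic synthetic-cohort generator with planted ground truth for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
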
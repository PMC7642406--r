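#' Simulate a cohort and write it to disk
#'
#' Materializes a full synthetic dataset: reference FASTA, GFF3 gene
#' models, one VCF per individual, DNA/RNA pileup TSVs, per-gene count
#' TSV, the planted-truth ledger as JSON, and a run manifest recording the
#' configuration so the run is reproducible.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created if absent).
#' @return Invisibly, a list of the in-memory objects (`genome_obj`,
#'   `individuals`, `pileups`) plus `paths`.
#' @export
run_simulate <- function(config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  genome_obj <- generate_genome(config)
  individuals <- generate_individuals(genome_obj, config)
  pileups <- generate_rna_pileups(genome_obj, individuals, config)
  p <- function(f) file.path(out_dir, f)
  write_genome(genome_obj, p("reference.fa"), p("annotation.gff3"))
  write_variants_vcf(individuals$WF, p("WF.vcf.gz"), "WF")
  write_variants_vcf(individuals$WM, p("WM.vcf.gz"), "WM")
  write_tsv(pileups$dna_pileups, p("dna_pileups.tsv"))
  write_tsv(pileups$rna_pileups, p("rna_pileups.tsv"))
  write_tsv(pileups$gene_counts, p("gene_counts.tsv"))
  truth <- list(variants = individuals$truth, editing = pileups$truth,
                library_sizes = as.list(pileups$library_sizes))
  jsonlite::write_json(truth, p("truth.json"), dataframe = "rows",
                       auto_unbox = TRUE, digits = NA)
  manifest <- list(
    tool = "variscape", step = "simulate",
    config = unclass(config)[!vapply(unclass(config), is.data.frame,
                                     logical(1))],
    outputs = c("reference.fa", "annotation.gff3", "WF.vcf.gz", "WM.vcf.gz",
                "dna_pileups.tsv", "rna_pileups.tsv", "gene_counts.tsv",
                "truth.json"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(genome_obj = genome_obj, individuals = individuals,
                 pileups = pileups, paths = out_dir))
}

#' Landscape summary tables for two individuals
#'
#' Hard-filters both call sets, annotates contexts, and computes the
#' genome-landscape summaries: Ti/Tv by context group, per-chromosome
#' frequencies with outlier fences, shared/exclusive counts, zygosity
#' tallies with het/non-reference-hom ratios, context percentages and
#' density bins.
#'
#' @param wf,wm variant tables for the two individuals.
#' @param genome_obj genome + models (from [generate_genome()] or read
#'   from files).
#' @param thresholds hard-filter thresholds.
#' @param bin_size density bin width in bp.
#' @param out_dir optional directory to write TSV/JSON outputs into.
#' @return List of summary tables.
#' @export
run_landscape <- function(wf, wm, genome_obj,
                          thresholds = filter_thresholds(),
                          bin_size = 10000, out_dir = NULL) {
  lens <- vapply(genome_obj$genome, length, integer(1))
  prep <- function(v) {
    v <- passing_variants(apply_hard_filters(v, thresholds))
    annotate_variants(v, genome_obj$models, genome_obj$genome)
  }
  wf <- prep(wf); wm <- prep(wm)
  titv_group <- function(v) {
    grp <- v$context
    grp[grp == "cds" & !is.na(v$impact) & v$impact == "synonymous"] <-
      "exon_synonymous"
    grp[grp == "cds"] <- "exon_non_synonymous"
    grp[grp %in% c("utr5", "utr3", "upstream", "downstream")] <- "other"
    grp
  }
  both <- rbind(cbind(wf, individual = "WF"), cbind(wm, individual = "WM"))
  snps <- both[both$kind == "snp", , drop = FALSE]
  ctx_bp <- context_sizes(genome_obj$models, lens)
  res <- list(
    titv = titv_ratio(snps, paste(snps$individual, titv_group(snps))),
    chrom_freq_snp = chromosome_frequencies(
      both[both$kind == "snp", ], lens),
    chrom_freq_indel = chromosome_frequencies(
      both[both$kind == "indel", ], lens),
    venn_snp = shared_exclusive(wf[wf$kind == "snp", ],
                                wm[wm$kind == "snp", ]),
    venn_indel = shared_exclusive(wf[wf$kind == "indel", ],
                                  wm[wm$kind == "indel", ]),
    zygosity = zygosity_summary(both, both$individual, both$context),
    context_pct = context_percentages(both$context, ctx_bp),
    density = density_bins(both, lens, bin_size)
  )
  freq <- res$chrom_freq_snp$frequency
  if (length(freq) >= 4) res$snp_fences <- tukey_fences(freq)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (nm in c("titv", "chrom_freq_snp", "chrom_freq_indel", "zygosity",
                 "context_pct", "density"))
      write_tsv(res[[nm]], file.path(out_dir, paste0(nm, ".tsv")))
    jsonlite::write_json(res[c("venn_snp", "venn_indel")],
                         file.path(out_dir, "venn.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  res
}

#' Sequencing and assembly metrics report
#'
#' @param mapping named list/vector of mapping category counts
#'   (`unique`, `non_unique`, `singletons`, `cross_contigs`), or `NULL`.
#' @param retention `data.frame(label, reads_kept, reads_total)`, or
#'   `NULL`.
#' @param coverage `data.frame(label, n_reads)` plus `read_length` /
#'   `genome_size` below, or `NULL`.
#' @param contigs contig sequences or lengths, or `NULL`.
#' @param read_length,genome_size coverage parameters (bp).
#' @param min_contig_len assembly filter (bp).
#' @param out_path optional JSON report path.
#' @return List of the computed metric blocks.
#' @export
run_metrics <- function(mapping = NULL, retention = NULL, coverage = NULL,
                        contigs = NULL, read_length = 125,
                        genome_size = 486e6, min_contig_len = 1000,
                        out_path = NULL) {
  res <- list()
  if (!is.null(mapping))
    res$mapping <- mapping_summary(mapping[["unique"]],
                                   mapping[["non_unique"]],
                                   mapping[["singletons"]],
                                   mapping[["cross_contigs"]])
  if (!is.null(retention))
    res$retention <- data.frame(
      label = retention$label,
      percent = mapply(retention_percent, retention$reads_kept,
                       retention$reads_total))
  if (!is.null(coverage))
    res$coverage <- data.frame(
      label = coverage$label,
      fold = vapply(coverage$n_reads, coverage_estimate, integer(1),
                    read_length = read_length, genome_size = genome_size))
  if (!is.null(contigs))
    res$assembly <- assembly_metrics(contigs, min_contig_len)
  if (!is.null(out_path))
    jsonlite::write_json(res, out_path, dataframe = "rows",
                         auto_unbox = TRUE, digits = NA)
  res
}

#' End-to-end RNA-editing analysis
#'
#' @param pileups list with `dna_pileups`, `rna_pileups`, `gene_counts`,
#'   `library_sizes` (as produced by [generate_rna_pileups()] or read
#'   from TSVs).
#' @param genome_obj genome + models.
#' @param region optional `list(chrom, start, end)` window of interest.
#' @param out_dir optional output directory.
#' @param ... thresholds passed to [detect_editing()].
#' @return List: `calls` (all site/sample rows), `summary` (from
#'   [annotate_editing()]).
#' @export
run_editing <- function(pileups, genome_obj, region = NULL, out_dir = NULL,
                        ...) {
  expr <- expression_table(pileups$gene_counts, genome_obj$models,
                           pileups$library_sizes)
  site_genes <- site_gene_map(pileups$rna_pileups, genome_obj$models)
  calls <- detect_editing(pileups$dna_pileups, pileups$rna_pileups, expr,
                          site_genes, ...)
  summary <- annotate_editing(calls, genome_obj$models, genome_obj$genome,
                              region)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv(calls, file.path(out_dir, "editing_calls.tsv"))
    write_tsv(summary$per_gene, file.path(out_dir, "editing_per_gene.tsv"))
    if (!is.null(summary$region))
      jsonlite::write_json(summary$region,
                           file.path(out_dir, "region_report.json"),
                           auto_unbox = TRUE, digits = NA)
  }
  list(calls = calls, summary = summary)
}

# map pileup sites to the gene whose exons contain them
site_gene_map <- function(pileups, models) {
  sites <- unique(pileups[, c("chrom", "pos")])
  ctx <- assign_context(sites, models, window = 0)
  data.frame(chrom = sites$chrom, pos = sites$pos, gene = ctx$gene_id,
             stringsAsFactors = FALSE)
}
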
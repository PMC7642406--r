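#' Reads per kilobase of exon model per million mapped reads
#'
#' `RPKM = 1e9 * gene_reads / (exon_model_length * total_mapped_reads)`,
#' the expression unit used to gate the editing analysis.
#'
#' @param gene_reads reads assigned to the gene.
#' @param exon_model_length total exon length of the gene in bp.
#' @param total_mapped_reads library size.
#' @return RPKM value(s); inputs recycle.
#' @examples
#' rpkm(1, 1000, 1e6)  # 1
#' @export
rpkm <- function(gene_reads, exon_model_length, total_mapped_reads) {
  if (any(exon_model_length <= 0) || any(total_mapped_reads <= 0))
    stop("exon model length and total mapped reads must be positive")
  if (any(gene_reads < 0)) stop("gene_reads must be non-negative")
  1e9 * gene_reads / (exon_model_length * total_mapped_reads)
}

#' Per-gene, per-sample expression table
#'
#' @param gene_counts `data.frame(gene_id, sample, reads)`.
#' @param models named list of [gene_model()] (exon lengths).
#' @param library_sizes named vector of total mapped reads per sample.
#' @return The table with an `rpkm` column added.
#' @export
expression_table <- function(gene_counts, models, library_sizes) {
  exon_len <- vapply(models, function(m) interval_bp(m$exons), numeric(1))
  missing_g <- setdiff(unique(gene_counts$gene_id), names(exon_len))
  if (length(missing_g))
    stop("gene(s) without a model: ", paste(missing_g, collapse = ", "))
  missing_s <- setdiff(unique(gene_counts$sample), names(library_sizes))
  if (length(missing_s))
    stop("sample(s) without a library size: ",
         paste(missing_s, collapse = ", "))
  gene_counts$rpkm <- rpkm(gene_counts$reads,
                           exon_len[gene_counts$gene_id],
                           library_sizes[gene_counts$sample])
  gene_counts
}

#' Prefilter transcriptome variant calls
#'
#' The upstream screen applied to raw RNA-seq variant calls before any
#' genome comparison. A call is discarded when (1) it lies within
#' `end_margin` bases of a sequence end, (2) the reference base is
#' ambiguous at or within `end_margin` bases of the site, (3) the average
#' copy number of the flanking region exceeds `max_copy_number`, (4) the
#' quality score of either allele is below `min_allele_quality`, (5)
#' either allele has fewer than `min_allele_reads` supporting reads, or
#' when the variant frequency or coverage falls below `min_frequency` /
#' `min_coverage`. The first failing rule is reported.
#'
#' @param calls `data.frame` with metadata columns `dist_to_end`,
#'   `ref_ambiguous` (logical), `copy_number`, `min_allele_quality`,
#'   `min_allele_reads`, `variant_frequency`, `coverage`.
#' @param end_margin,max_copy_number,min_allele_quality,min_allele_reads,min_frequency,min_coverage
#'   thresholds (defaults 60, 2, 20, 2, 0.15, 4).
#' @param strict error on missing metadata instead of skipping the rule.
#' @return `calls` with logical `keep` and character `reason` columns
#'   ("" when kept).
#' @export
rna_variant_prefilter <- function(calls, end_margin = 60,
                                  max_copy_number = 2,
                                  min_allele_quality = 20,
                                  min_allele_reads = 2,
                                  min_frequency = 0.15, min_coverage = 4,
                                  strict = FALSE) {
  rules <- list(
    end_proximity = calls$dist_to_end < end_margin,
    ambiguous_reference = as.logical(calls$ref_ambiguous),
    copy_number = calls$copy_number > max_copy_number,
    allele_quality = calls$min_allele_quality < min_allele_quality,
    allele_support = calls$min_allele_reads < min_allele_reads,
    variant_frequency = calls$variant_frequency < min_frequency,
    coverage = calls$coverage < min_coverage
  )
  if (strict && any(vapply(rules, anyNA, logical(1))))
    stop("missing prefilter metadata in strict mode")
  reason <- rep("", nrow(calls))
  for (nm in names(rules)) {
    fail <- !is.na(rules[[nm]]) & rules[[nm]]
    reason[reason == "" & fail] <- nm
  }
  calls$keep <- reason == ""
  calls$reason <- reason
  calls
}

#' Allele profile of a site pileup
#'
#' Bases supported by at least `support_frac` of the covering reads are
#' retained; anything rarer is treated as sequencing error and discarded.
#' The locus is homozygous when the dominant retained allele reaches a
#' frequency of `hom_frac`, heterozygous below it. Both comparisons are
#' boundary-inclusive (a base at exactly 10% is retained; a dominant
#' allele at exactly 0.90 is homozygous).
#'
#' @param counts named counts for `A`, `C`, `G`, `T` (list, vector or
#'   one-row pileup `data.frame`).
#' @param support_frac minimum read fraction to retain an allele
#'   (default 0.10).
#' @param hom_frac dominant-allele frequency at or above which the locus
#'   is homozygous (default 0.90).
#' @return List: `alleles` (named frequencies of retained bases, sorted
#'   decreasing), `zygosity` (`"homozygous"`/`"heterozygous"`), `depth`.
#' @export
allele_profile <- function(counts, support_frac = 0.10, hom_frac = 0.90) {
  if (is.data.frame(counts)) counts <- as.list(counts[1, ])
  cnt <- vapply(dna_bases, function(b)
    as.numeric(if (is.null(counts[[b]]) || is.na(counts[[b]])) 0
               else counts[[b]]), numeric(1))
  depth <- sum(cnt)
  if (depth <= 0) stop("allele_profile needs positive depth")
  freq <- cnt / depth
  kept <- freq[freq >= support_frac]
  kept <- sort(kept, decreasing = TRUE)
  list(alleles = kept,
       zygosity = if (kept[1] >= hom_frac) "homozygous" else "heterozygous",
       depth = depth)
}

#' Coverage, expression and indel gate for a DNA/RNA site pair
#'
#' A site enters the editing comparison only when DNA and RNA coverage
#' simultaneously reach `min_coverage`, the host gene is expressed
#' (RPKM at or above `min_rpkm`) in every one of the six RNA samples, and
#' there is no insertion/deletion evidence at the site.
#'
#' @param dna_depth,rna_depth read depths at the site.
#' @param rpkm_values the gene's RPKM in all RNA samples.
#' @param has_indel any del/ins evidence at the site.
#' @param min_coverage simultaneous DNA and RNA depth bound (default 5).
#' @param min_rpkm expression bound (default 1).
#' @param n_samples number of RNA samples the expression gate expects
#'   (default 6).
#' @return List: `pass` (logical), `reasons` (character, empty if pass).
#' @export
site_passes_filters <- function(dna_depth, rna_depth, rpkm_values,
                                has_indel = FALSE, min_coverage = 5,
                                min_rpkm = 1, n_samples = 6) {
  if (length(rpkm_values) != n_samples || anyNA(rpkm_values))
    stop("expression gate needs RPKM for all ", n_samples, " samples")
  reasons <- character(0)
  if (dna_depth < min_coverage) reasons <- c(reasons, "dna_coverage")
  if (rna_depth < min_coverage) reasons <- c(reasons, "rna_coverage")
  if (any(rpkm_values < min_rpkm)) reasons <- c(reasons, "expression")
  if (isTRUE(has_indel)) reasons <- c(reasons, "indel_evidence")
  list(pass = length(reasons) == 0, reasons = reasons)
}

#' Call RNA editing from matched allele profiles
#'
#' An RNA-retained base that is absent from the DNA allele profile is an
#' editing signal: the transcript carries a nucleotide unsupported by the
#' individual's genome. The call is a `two_variant` event when a genomic
#' allele is still RNA-retained alongside the edited base (edited and
#' unedited transcripts co-occur) and a `full_edit` when only the edited
#' form is seen. In `strict` mode the edited base must have zero genome
#' reads, not merely sub-threshold support.
#'
#' @param dna_profile,rna_profile from [allele_profile()].
#' @param dna_counts raw DNA base counts; required for `strict`.
#' @param strict require zero genomic reads of the edited base.
#' @return List: `mode` (`"none"`, `"two_variant"`, `"full_edit"`),
#'   `from_base` (dominant DNA allele), `to_base` (`NA` if none).
#' @export
call_editing <- function(dna_profile, rna_profile, dna_counts = NULL,
                         strict = FALSE) {
  dna_alleles <- names(dna_profile$alleles)
  rna_alleles <- names(rna_profile$alleles)
  novel <- setdiff(rna_alleles, dna_alleles)
  if (strict && length(novel)) {
    if (is.null(dna_counts)) stop("strict mode needs raw DNA counts")
    if (is.data.frame(dna_counts)) dna_counts <- as.list(dna_counts[1, ])
    novel <- novel[vapply(novel, function(b)
      as.numeric(dna_counts[[b]]) == 0, logical(1))]
  }
  from <- dna_alleles[1]
  if (length(novel) == 0)
    return(list(mode = "none", from_base = from, to_base = NA_character_))
  # most frequent novel base is the reported edit
  to <- novel[which.max(rna_profile$alleles[novel])]
  mode <- if (any(dna_alleles %in% rna_alleles)) "two_variant" else "full_edit"
  list(mode = mode, from_base = from, to_base = to)
}

#' Detect RNA editing across a cohort of pileups
#'
#' Runs the full cascade for every (site, RNA sample) pair: the
#' simultaneous coverage / expression / indel gate, allele profiling of
#' the matched DNA (the individual owning the RNA sample) and RNA
#' pileups, and the editing comparison. RNA sample ids are mapped to DNA
#' individuals by their prefix before the first underscore (WF_B -> WF).
#'
#' @param dna_pileups,rna_pileups pileup tables
#'   (`chrom, pos, sample, A, C, G, T, del, ins`).
#' @param expression from [expression_table()].
#' @param site_genes `data.frame(chrom, pos, gene)` mapping sites to the
#'   gene whose expression gates them.
#' @param support_frac,hom_frac,min_coverage,min_rpkm thresholds (see
#'   [allele_profile()], [site_passes_filters()]).
#' @param strict zero-genomic-read rule for the edited base.
#' @return `data.frame` with one row per (site, sample):
#'   `chrom, pos, sample, gene, pass, reasons, mode, from_base, to_base`.
#'   Rows failing the gate carry `mode = NA`; passing rows with no signal
#'   carry `mode = "none"`.
#' @export
detect_editing <- function(dna_pileups, rna_pileups, expression, site_genes,
                           support_frac = 0.10, hom_frac = 0.90,
                           min_coverage = 5, min_rpkm = 1, strict = FALSE) {
  samples <- sort(unique(rna_pileups$sample))
  n_samples <- length(samples)
  key <- function(df) paste(df$chrom, df$pos)
  site_key <- key(site_genes)
  out <- list()
  for (i in seq_len(nrow(rna_pileups))) {
    r <- rna_pileups[i, ]
    ind <- sub("_.*$", "", r$sample)
    d <- dna_pileups[dna_pileups$chrom == r$chrom &
                       dna_pileups$pos == r$pos &
                       dna_pileups$sample == ind, , drop = FALSE]
    gene <- site_genes$gene[match(paste(r$chrom, r$pos), site_key)]
    row <- data.frame(chrom = r$chrom, pos = r$pos, sample = r$sample,
                      gene = if (is.na(gene)) NA_character_ else gene,
                      pass = FALSE, reasons = "", mode = NA_character_,
                      from_base = NA_character_, to_base = NA_character_,
                      stringsAsFactors = FALSE)
    if (nrow(d) == 0) {
      row$reasons <- "no_matched_dna"
      out[[length(out) + 1]] <- row; next
    }
    if (is.na(gene)) {
      row$reasons <- "no_gene_assignment"
      out[[length(out) + 1]] <- row; next
    }
    rpkms <- expression$rpkm[expression$gene_id == gene]
    if (length(rpkms) != n_samples) {
      row$reasons <- "incomplete_expression"
      out[[length(out) + 1]] <- row; next
    }
    base_cols <- c(dna_bases, "del", "ins")
    dna_counts <- as.list(d[1, base_cols])
    rna_counts <- as.list(r[base_cols])
    dna_depth <- sum(unlist(dna_counts[dna_bases]))
    rna_depth <- sum(unlist(rna_counts[dna_bases]))
    has_indel <- (dna_counts$del + dna_counts$ins +
                    rna_counts$del + rna_counts$ins) > 0
    gate <- site_passes_filters(dna_depth, rna_depth, rpkms, has_indel,
                                min_coverage, min_rpkm, n_samples)
    if (!gate$pass) {
      row$reasons <- paste(gate$reasons, collapse = ";")
      out[[length(out) + 1]] <- row; next
    }
    dp <- allele_profile(dna_counts, support_frac, hom_frac)
    rp <- allele_profile(rna_counts, support_frac, hom_frac)
    call <- call_editing(dp, rp, dna_counts = dna_counts, strict = strict)
    row$pass <- TRUE
    row$mode <- call$mode
    row$from_base <- call$from_base
    row$to_base <- call$to_base
    out[[length(out) + 1]] <- row
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(chrom = character(0), pos = integer(0),
                      sample = character(0), gene = character(0),
                      pass = logical(0), reasons = character(0),
                      mode = character(0), from_base = character(0),
                      to_base = character(0), stringsAsFactors = FALSE)
  res
}

#' Annotate editing calls and summarize per gene and region
#'
#' Adds genomic context and, for CDS edits, the synonymous /
#' non-synonymous impact of the base change, then tabulates events per
#' gene and per sample and counts calls inside and outside a genomic
#' window of interest (e.g. a sex-determining region).
#'
#' @param calls output of [detect_editing()]; only rows with
#'   `mode != "none"` are summarized.
#' @param models named list of gene models.
#' @param genome named `DNAStringSet`.
#' @param region optional `list(chrom=, start=, end=)` window.
#' @return List: `calls` (annotated event rows), `per_gene`
#'   (`gene, sample, events, cds_events, non_cds_events`), `region`
#'   (`inside`, `outside` counts; `NULL` when no window given).
#' @export
annotate_editing <- function(calls, models, genome, region = NULL) {
  ev <- calls[!is.na(calls$mode) & calls$mode != "none", , drop = FALSE]
  if (nrow(ev)) {
    fake <- data.frame(chrom = ev$chrom, pos = ev$pos, stringsAsFactors = FALSE)
    ctx <- assign_context(fake, models)
    ev$context <- ctx$context
    ev$impact <- NA_character_
    for (i in which(ev$context == "cds")) {
      m <- models[[ctx$gene_id[i]]]
      ev$impact[i] <- classify_snp_effect(ev$pos[i], ev$from_base[i],
                                          ev$to_base[i], m, genome)
    }
  } else {
    ev$context <- character(0)
    ev$impact <- character(0)
  }
  per_gene <- if (nrow(ev)) {
    strata <- unique(ev[, c("gene", "sample")])
    do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
      sel <- ev$gene == strata$gene[i] & ev$sample == strata$sample[i]
      data.frame(gene = strata$gene[i], sample = strata$sample[i],
                 events = sum(sel),
                 cds_events = sum(sel & ev$context == "cds"),
                 non_cds_events = sum(sel & ev$context != "cds"),
                 stringsAsFactors = FALSE)
    }))
  } else {
    data.frame(gene = character(0), sample = character(0),
               events = integer(0), cds_events = integer(0),
               non_cds_events = integer(0), stringsAsFactors = FALSE)
  }
  region_counts <- NULL
  if (!is.null(region)) {
    inside <- ev$chrom == region$chrom & ev$pos >= region$start &
      ev$pos <= region$end
    region_counts <- list(inside = sum(inside), outside = sum(!inside))
  }
  list(calls = ev, per_gene = per_gene, region = region_counts)
}
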
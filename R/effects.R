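context_precedence <- c("cds", "utr5", "utr3", "intron", "upstream",
                        "downstream", "intergenic")

#' Genomic context of variants relative to gene models
#'
#' Assigns each variant exactly one context label with the precedence
#' `cds > utr5/utr3 > intron > upstream > downstream > intergenic` — when
#' several features or neighbouring genes apply, the most gene-proximal
#' ("most relevant") context wins, e.g. a position that is downstream of
#' one gene and upstream of the next is labelled upstream. Upstream and
#' downstream are strand-aware windows (default 5 kbp) on the 5' and 3'
#' sides of each gene on its own strand. Ties between genes offering the
#' same context class go to the gene with the smaller span, then the
#' lexicographically smaller id.
#'
#' @param variants variant `data.frame` (chrom/pos used; for indels the
#'   anchor position is used).
#' @param models named list of [gene_model()] objects.
#' @param window upstream/downstream window in bp.
#' @return `data.frame` with `context` and `gene_id` (`NA` for intergenic),
#'   one row per variant.
#' @export
assign_context <- function(variants, models, window = 5000) {
  n <- nrow(variants)
  context <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  if (n == 0 || length(models) == 0)
    return(data.frame(context = context, gene_id = gene_id,
                      stringsAsFactors = FALSE))
  model_chroms <- vapply(models, `[[`, character(1), "chrom")
  known <- variants$chrom %in% model_chroms
  if (any(!known) && length(unique(variants$chrom[!known])) > 0)
    warning("variants on chromosome(s) without annotation: ",
            paste(unique(variants$chrom[!known]), collapse = ", "),
            " -> intergenic")
  rank <- stats::setNames(seq_along(context_precedence), context_precedence)
  spans <- vapply(models, function(m) m$end - m$start + 1, numeric(1))
  for (i in which(known)) {
    p <- variants$pos[i]
    best <- c(rank[["intergenic"]], NA, NA)  # rank, span, gene index
    for (j in which(model_chroms == variants$chrom[i])) {
      m <- models[[j]]
      ctx <- position_context(m, p, window)
      if (is.na(ctx)) next
      r <- rank[[ctx]]
      better <- r < best[1] ||
        (r == best[1] && !is.na(best[2]) && spans[j] < best[2]) ||
        (r == best[1] && !is.na(best[2]) && spans[j] == best[2] &&
           m$gene_id < models[[best[3]]]$gene_id)
      if (better) best <- c(r, spans[j], j)
    }
    context[i] <- context_precedence[best[1]]
    if (!is.na(best[3])) gene_id[i] <- models[[best[3]]]$gene_id
  }
  data.frame(context = context, gene_id = gene_id, stringsAsFactors = FALSE)
}

# context of a single position w.r.t. one gene; NA when outside all windows
position_context <- function(m, p, window) {
  in_iv <- function(iv) nrow(iv) > 0 && any(iv$start <= p & iv$end >= p)
  if (p >= m$start && p <= m$end) {
    if (in_iv(m$cds)) return("cds")
    if (in_iv(m$utr5)) return("utr5")
    if (in_iv(m$utr3)) return("utr3")
    return("intron")
  }
  before <- p < m$start && p >= m$start - window
  after <- p > m$end && p <= m$end + window
  if (m$strand == "+") {
    if (before) return("upstream")
    if (after) return("downstream")
  } else {
    if (after) return("upstream")
    if (before) return("downstream")
  }
  NA_character_
}

#' Genome bp occupied by each context class
#'
#' Partitions every base of the genome into the context classes under the
#' same precedence as [assign_context()], giving the denominators for
#' percent-of-region-affected summaries.
#'
#' @param models named list of gene models.
#' @param chrom_lengths named chromosome lengths (bp).
#' @param window upstream/downstream window in bp.
#' @return Named numeric vector of bp per context class.
#' @export
context_sizes <- function(models, chrom_lengths, window = 5000) {
  si <- GenomeInfoDb::Seqinfo(names(chrom_lengths),
                              as.integer(chrom_lengths))
  mk <- function(chrom, start, end) {
    start <- pmax(start, 1)
    end <- pmin(end, unname(chrom_lengths[chrom]))
    keep <- end >= start
    GenomicRanges::GRanges(chrom[keep],
                           IRanges::IRanges(start[keep], end[keep]),
                           seqinfo = si)
  }
  collect <- function(field) {
    parts <- lapply(models, function(m) {
      iv <- m[[field]]
      if (nrow(iv) == 0) return(NULL)
      mk(rep(m$chrom, nrow(iv)), iv$start, iv$end)
    })
    parts <- parts[!vapply(parts, is.null, logical(1))]
    if (length(parts) == 0) return(GenomicRanges::GRanges(seqinfo = si))
    GenomicRanges::reduce(do.call(c, unname(parts)))
  }
  cds <- collect("cds")
  utr5 <- collect("utr5"); utr3 <- collect("utr3")
  genes <- GenomicRanges::reduce(do.call(c, unname(lapply(models, function(m)
    mk(m$chrom, m$start, m$end)))))
  up <- GenomicRanges::reduce(do.call(c, unname(lapply(models, function(m) {
    if (m$strand == "+") mk(m$chrom, m$start - window, m$start - 1)
    else mk(m$chrom, m$end + 1, m$end + window)
  }))))
  down <- GenomicRanges::reduce(do.call(c, unname(lapply(models, function(m) {
    if (m$strand == "+") mk(m$chrom, m$end + 1, m$end + window)
    else mk(m$chrom, m$start - window, m$start - 1)
  }))))
  higher <- GenomicRanges::GRanges(seqinfo = si)
  take <- function(gr) {
    out <- GenomicRanges::setdiff(gr, higher)
    higher <<- GenomicRanges::reduce(c(higher, gr))
    sum(GenomicRanges::width(out))
  }
  sizes <- c(
    cds = take(cds),
    utr5 = take(utr5),
    utr3 = take(utr3),
    # after removing cds/utr bp, the remaining gene-body bp are intronic
    # (exons partition into cds and utrs in these models)
    intron = take(genes),
    upstream = take(up),
    downstream = take(down)
  )
  sizes["intergenic"] <- sum(chrom_lengths) - sum(sizes)
  sizes
}

# VCF-style parsimony: strip shared suffix then shared prefix, keeping at
# least one base of each allele; returns normalized ref/alt and position.
left_normalize <- function(pos, ref, alt) {
  r <- strsplit(ref, "")[[1]]; a <- strsplit(alt, "")[[1]]
  while (length(r) > 1 && length(a) > 1 && r[length(r)] == a[length(a)]) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  list(pos = pos, ref = paste(r, collapse = ""),
       alt = paste(a, collapse = ""))
}

codon_table <- function() Biostrings::GENETIC_CODE

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) NA_character_ else aa
}

#' Protein-level impact of a coding SNP
#'
#' Rebuilds the codon containing the site on the coding strand (reverse
#' complement for minus-strand genes), translates before and after with
#' the standard nuclear genetic code, and labels the change.
#'
#' @param pos genomic position of the SNP.
#' @param ref,alt single-base alleles on the forward genomic strand.
#' @param model the [gene_model()] containing the site in its CDS.
#' @param genome named `DNAStringSet`.
#' @return One of `"synonymous"`, `"non_synonymous"`, `"stop_gained"`,
#'   `"stop_lost"`, `"start_lost"`.
#' @export
classify_snp_effect <- function(pos, ref, alt, model, genome) {
  stopifnot(nchar(ref) == 1, nchar(alt) == 1)
  off <- cds_offset(model, pos)
  if (is.na(off)) stop("SNP position maps outside the CDS")
  cds <- as.character(coding_sequence(model, genome))
  base_ref <- if (model$strand == "+") ref else comp_base(ref)
  base_alt <- if (model$strand == "+") alt else comp_base(alt)
  if (substr(cds, off + 1, off + 1) != base_ref)
    stop("reference allele disagrees with the reference sequence at ",
         model$chrom, ":", pos)
  codon_i <- off %/% 3
  within <- off %% 3
  old_codon <- substr(cds, codon_i * 3 + 1, codon_i * 3 + 3)
  new_codon <- old_codon
  substr(new_codon, within + 1, within + 1) <- base_alt
  old_aa <- translate_codon(old_codon)
  new_aa <- translate_codon(new_codon)
  if (codon_i == 0 && old_codon == "ATG" && new_codon != "ATG")
    return("start_lost")
  if (old_aa != "*" && new_aa == "*") return("stop_gained")
  if (old_aa == "*" && new_aa != "*") return("stop_lost")
  if (old_aa == new_aa) "synonymous" else "non_synonymous"
}

comp_base <- function(b)
  c(A = "T", C = "G", G = "C", T = "A")[[b]]

#' Protein-level impact of a coding indel
#'
#' Alleles are left-normalized (VCF parsimony) first. An indel whose net
#' length change is not a multiple of 3 shifts the reading frame; in-frame
#' events are classified by their alignment to codon boundaries: a
#' deletion removing whole codons is a simple codon deletion and an
#' insertion at a codon boundary a simple codon insertion, while in-frame
#' events that straddle a boundary also change a flanking codon
#' (codon change + deletion / insertion).
#'
#' @param pos anchor position (VCF convention: first ref base shared).
#' @param ref,alt allele strings, forward genomic strand.
#' @param model the containing [gene_model()].
#' @return One of `"frameshift"`, `"codon_deletion"`, `"codon_insertion"`,
#'   `"codon_change_plus_deletion"`, `"codon_change_plus_insertion"`.
#' @export
classify_indel_effect <- function(pos, ref, alt, model) {
  norm <- left_normalize(pos, ref, alt)
  pos <- norm$pos; ref <- norm$ref; alt <- norm$alt
  net <- nchar(alt) - nchar(ref)
  if (net == 0) stop("not an indel after normalization")
  if (net %% 3 != 0) return("frameshift")
  if (net < 0) {
    # deleted bases occupy pos+1 .. pos+|net| (anchor base retained)
    del_pos <- (pos + 1):(pos + abs(net))
    offs <- cds_offset(model, del_pos)
    if (anyNA(offs)) return("frameshift")  # deletion runs off the CDS edge
    if (min(offs) %% 3 == 0) "codon_deletion" else
      "codon_change_plus_deletion"
  } else {
    # insertion between pos and pos+1
    o_anchor <- cds_offset(model, pos)
    if (is.na(o_anchor)) stop("indel anchor maps outside the CDS")
    point <- if (model$strand == "+") o_anchor + 1 else o_anchor
    if (point %% 3 == 0) "codon_insertion" else
      "codon_change_plus_insertion"
  }
}

#' Annotate a variant table with context and impact
#'
#' Adds `context`, `gene_id` and `impact` columns. Impact is computed for
#' CDS variants only (`NA` elsewhere); multi-allelic records are annotated
#' by their first alternate allele.
#'
#' @param variants variant `data.frame`.
#' @param models named list of gene models.
#' @param genome named `DNAStringSet`.
#' @param window upstream/downstream window in bp.
#' @return The annotated table.
#' @export
annotate_variants <- function(variants, models, genome, window = 5000) {
  ctx <- assign_context(variants, models, window)
  variants$context <- ctx$context
  variants$gene_id <- ctx$gene_id
  variants$impact <- NA_character_
  for (i in which(variants$context == "cds")) {
    m <- models[[variants$gene_id[i]]]
    alt1 <- strsplit(variants$alt[i], ",", fixed = TRUE)[[1]][1]
    variants$impact[i] <- if (variants$kind[i] == "snp" &&
                              nchar(alt1) == 1 && nchar(variants$ref[i]) == 1)
      classify_snp_effect(variants$pos[i], variants$ref[i], alt1, m, genome)
    else
      classify_indel_effect(variants$pos[i], variants$ref[i], alt1, m)
  }
  variants
}
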
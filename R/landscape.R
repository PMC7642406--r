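#' Transition/transversion ratio, optionally by group
#'
#' Ratio of transition SNPs (A<->G, C<->T) to transversion SNPs. Under a
#' uniform substitution model the expectation is 0.5 (two transition
#' pairings against four transversion pairings); real genomes sit well
#' above it, and the ratio shifts with genomic context, so it is computed
#' per group (e.g. intron / exon-synonymous / exon-non-synonymous /
#' intergenic).
#'
#' Multi-allelic SNPs contribute one substitution per alternate allele.
#'
#' @param variants variant `data.frame`; only rows with `kind == "snp"`
#'   are used.
#' @param group optional factor/character of the same length as
#'   `nrow(variants)` to stratify by.
#' @return A `data.frame` with `group`, `transitions`, `transversions` and
#'   `titv` (`NA` when there are no transversions — the ratio is undefined
#'   rather than infinite).
#' @export
titv_ratio <- function(variants, group = NULL) {
  if (is.null(group)) group <- rep("all", nrow(variants))
  stopifnot(length(group) == nrow(variants))
  snp <- variants$kind == "snp"
  variants <- variants[snp, , drop = FALSE]
  group <- as.character(group)[snp]
  # expand multi-allelic records to one substitution per alt allele
  alts <- strsplit(variants$alt, ",", fixed = TRUE)
  n_alt <- lengths(alts)
  ref <- rep(variants$ref, n_alt)
  alt <- unlist(alts, use.names = FALSE)
  grp <- rep(group, n_alt)
  ti <- if (length(ref)) is_transition(ref, alt) else logical(0)
  levels <- unique(c(grp, character(0)))
  out <- do.call(rbind, lapply(levels, function(g) {
    sel <- grp == g
    n_ti <- sum(ti[sel])
    n_tv <- sum(!ti[sel])
    data.frame(group = g, transitions = n_ti, transversions = n_tv,
               titv = if (n_tv > 0) n_ti / n_tv else NA_real_,
               stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(group = character(0), transitions = integer(0),
                      transversions = integer(0), titv = numeric(0),
                      stringsAsFactors = FALSE)
  out
}

#' Per-chromosome event frequencies
#'
#' Number of events per chromosome divided by chromosome length, the
#' per-base frequency used to compare chromosomes of different sizes.
#' Virtual chromosomes — placeholder bins such as "chrUn" or "*_random"
#' holding sequence not assigned to a real chromosome — can be excluded.
#'
#' @param variants variant `data.frame`.
#' @param chrom_lengths named numeric vector of chromosome lengths (bp).
#' @param drop_virtual exclude virtual chromosomes before tallying.
#' @param virtual_patterns regular expressions identifying virtual
#'   chromosome names.
#' @return A `data.frame` with `chrom`, `event_count`, `chrom_length`,
#'   `frequency` and `percent` (= 100 x frequency), one row per retained
#'   chromosome (zero counts included).
#' @export
chromosome_frequencies <- function(variants, chrom_lengths,
                                   drop_virtual = TRUE,
                                   virtual_patterns = c("^Un$", "^chrUn",
                                                        "_random$")) {
  unknown <- setdiff(unique(variants$chrom), names(chrom_lengths))
  if (length(unknown))
    stop("variants on chromosomes with no declared length: ",
         paste(unknown, collapse = ", "))
  keep <- names(chrom_lengths)
  if (drop_virtual) {
    virt <- Reduce(`|`, lapply(virtual_patterns, function(p) grepl(p, keep)),
                   init = rep(FALSE, length(keep)))
    keep <- keep[!virt]
  }
  counts <- table(factor(variants$chrom, levels = keep))
  data.frame(
    chrom = keep,
    event_count = as.integer(counts),
    chrom_length = unname(chrom_lengths[keep]),
    frequency = as.integer(counts) / unname(chrom_lengths[keep]),
    percent = 100 * as.integer(counts) / unname(chrom_lengths[keep]),
    stringsAsFactors = FALSE
  )
}

#' Tukey's fences for outlier screening
#'
#' Fences at `Q1 - k*IQR` and `Q3 + k*IQR`; values strictly outside the
#' fences are flagged as outliers. Quartiles use linear interpolation
#' (`stats::quantile` type 7, the R default); the convention is pluggable
#' through `qtype`.
#'
#' @param values numeric vector, at least 4 values.
#' @param k fence multiplier (default 1.5, the conventional choice).
#' @param qtype quantile algorithm passed to [stats::quantile()].
#' @return A list with `lower`, `upper`, and logical `outlier` flags.
#' @examples
#' tukey_fences(c(1, 2, 3, 4, 5, 100))
#' @export
tukey_fences <- function(values, k = 1.5, qtype = 7) {
  if (length(values) < 4)
    stop("tukey_fences needs at least 4 values")
  q <- stats::quantile(values, c(0.25, 0.75), type = qtype, names = FALSE)
  iqr <- q[2] - q[1]
  lower <- q[1] - k * iqr
  upper <- q[2] + k * iqr
  list(lower = lower, upper = upper,
       outlier = values < lower | values > upper)
}

#' Variant set keys
#'
#' Identity of a variant for set comparisons: chromosome, position,
#' reference and alternate alleles.
#' @param variants variant `data.frame`.
#' @return character vector of keys.
#' @export
variant_keys <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}

#' Shared and exclusive variant counts between two individuals
#'
#' The three disjoint Venn classes of two variant sets keyed by
#' (chrom, pos, ref, alt).
#'
#' @param keys_a,keys_b character vectors of variant keys (or variant
#'   tables, in which case [variant_keys()] is applied).
#' @return Named list: `shared`, `only_a`, `only_b`.
#' @export
shared_exclusive <- function(keys_a, keys_b) {
  if (is.data.frame(keys_a)) keys_a <- variant_keys(keys_a)
  if (is.data.frame(keys_b)) keys_b <- variant_keys(keys_b)
  a <- unique(keys_a); b <- unique(keys_b)
  list(shared = length(intersect(a, b)),
       only_a = length(setdiff(a, b)),
       only_b = length(setdiff(b, a)))
}

#' Heterozygous / homozygous ratio from counts
#'
#' @param het heterozygous count (0/1 plus 1/2 loci).
#' @param hom non-reference homozygous count (1/1 loci).
#' @return `het / hom`, or `NA` when `hom` is zero.
#' @examples
#' het_hom_ratio(4104719, 2281366)  # 1.80
#' @export
het_hom_ratio <- function(het, hom) {
  if (hom == 0) return(NA_real_)
  het / hom
}

#' Zygosity tallies and het/non-reference-hom ratios
#'
#' Tallies genotype classes per individual and variant kind, with the
#' heterozygous count defined as 0/1 plus 1/2 loci and the homozygous
#' count as non-reference 1/1 loci (0/0 records are excluded from both).
#' An optional `group` stratifies further, e.g. by genomic context.
#'
#' @param variants variant `data.frame`.
#' @param individual character vector naming the individual per row (or a
#'   single id).
#' @param group optional per-row stratum.
#' @return A `data.frame` with per-stratum counts of `het_ref_alt`,
#'   `het_alt_alt`, `hom_alt`, the combined `het` count and the
#'   `het_nonref_hom` ratio (`NA` when the homozygous count is zero).
#' @export
zygosity_summary <- function(variants, individual = "all", group = NULL) {
  n <- nrow(variants)
  individual <- rep_len(as.character(individual), n)
  group <- if (is.null(group)) rep("all", n) else rep_len(as.character(group), n)
  keep <- variants$genotype_class %in% c("het_ref_alt", "het_alt_alt", "hom_alt")
  df <- data.frame(individual = individual[keep], kind = variants$kind[keep],
                   group = group[keep], class = variants$genotype_class[keep],
                   stringsAsFactors = FALSE)
  strata <- unique(df[, c("individual", "kind", "group")])
  if (nrow(strata) == 0)
    return(data.frame(individual = character(0), kind = character(0),
                      group = character(0), het_ref_alt = integer(0),
                      het_alt_alt = integer(0), hom_alt = integer(0),
                      het = integer(0), het_nonref_hom = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, lapply(seq_len(nrow(strata)), function(i) {
    s <- strata[i, ]
    cls <- df$class[df$individual == s$individual & df$kind == s$kind &
                      df$group == s$group]
    n01 <- sum(cls == "het_ref_alt")
    n12 <- sum(cls == "het_alt_alt")
    n11 <- sum(cls == "hom_alt")
    data.frame(individual = s$individual, kind = s$kind, group = s$group,
               het_ref_alt = n01, het_alt_alt = n12, hom_alt = n11,
               het = n01 + n12,
               het_nonref_hom = het_hom_ratio(n01 + n12, n11),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Percentage of each genomic context affected by events
#'
#' @param context character vector of context labels, one per variant.
#' @param context_bp named numeric vector: total bp of each context class
#'   in the genome (see [context_sizes()]).
#' @return `data.frame` with `context`, `events`, `bp`, `percent`
#'   (= 100 x events / bp).
#' @export
context_percentages <- function(context, context_bp) {
  ctx <- unique(context)
  missing_bp <- setdiff(ctx, names(context_bp))
  if (length(missing_bp))
    stop("no size supplied for context(s): ",
         paste(missing_bp, collapse = ", "))
  counts <- table(factor(context, levels = names(context_bp)))
  data.frame(
    context = names(context_bp),
    events = as.integer(counts),
    bp = unname(context_bp),
    percent = 100 * as.integer(counts) / unname(context_bp),
    stringsAsFactors = FALSE
  )
}

#' Binned variant counts along chromosomes
#'
#' Counts events in fixed-width windows, the input for density heatmaps.
#'
#' @param variants variant `data.frame`.
#' @param chrom_lengths named lengths in bp.
#' @param bin_size window width in bp.
#' @return `data.frame` with `chrom`, `bin_start` (1-based), `bin_end`,
#'   `count`; bins partition each chromosome, so counts sum to the number
#'   of variants.
#' @export
density_bins <- function(variants, chrom_lengths, bin_size) {
  stopifnot(bin_size > 0)
  out <- do.call(rbind, lapply(names(chrom_lengths), function(ch) {
    len <- chrom_lengths[[ch]]
    n_bins <- max(1L, as.integer(ceiling(len / bin_size)))
    starts <- (seq_len(n_bins) - 1L) * bin_size + 1L
    pos <- variants$pos[variants$chrom == ch]
    idx <- pmin(((pos - 1L) %/% bin_size) + 1L, n_bins)
    counts <- tabulate(idx, nbins = n_bins)
    data.frame(chrom = ch, bin_start = starts,
               bin_end = pmin(starts + bin_size - 1L, len),
               count = counts, stringsAsFactors = FALSE)
  }))
  if (is.null(out))
    out <- data.frame(chrom = character(0), bin_start = integer(0),
                      bin_end = integer(0), count = integer(0))
  out
}
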
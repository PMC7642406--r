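#' Summarize read-mapping categories
#'
#' Builds a mapping summary (counts and percentages of total mapped reads)
#' from flagstat-like category counts: reads mapping uniquely, reads mapping
#' to multiple sites, singletons (mate lost) and cross-contig pairs (mate on
#' a different reference sequence).
#'
#' @param unique_reads number of uniquely mapping reads.
#' @param non_unique number of multi-mapping reads.
#' @param singletons number of reads whose mate was lost.
#' @param cross_contigs number of reads whose mate maps elsewhere.
#' @param total_mapped total mapped reads; defaults to `unique_reads +
#'   non_unique` (the two classes partition the total).
#' @return A `data.frame` with one row per category: `category`, `count`,
#'   `percent` (of total mapped, rounded to 2 decimal places).
#' @examples
#' mapping_summary(187424438, 22198252, 1782319, 20897087)
#' @export
mapping_summary <- function(unique_reads, non_unique, singletons = 0,
                            cross_contigs = 0,
                            total_mapped = unique_reads + non_unique) {
  counts <- c(unique_reads, non_unique, singletons, cross_contigs, total_mapped)
  if (any(!is.finite(counts)) || any(counts < 0))
    stop("mapping category counts must be non-negative numbers")
  if (total_mapped <= 0) stop("total mapped reads must be > 0")
  if (unique_reads + non_unique != total_mapped)
    stop("unique + non-unique must equal total mapped reads")
  cat_counts <- c(total_mapped = total_mapped, unique = unique_reads,
                  non_unique = non_unique, singletons = singletons,
                  cross_contigs = cross_contigs)
  data.frame(
    category = names(cat_counts),
    count = unname(cat_counts),
    percent = round(100 * unname(cat_counts) / total_mapped, 2),
    stringsAsFactors = FALSE
  )
}

#' Percentage of reads retained after quality trimming
#'
#' @param reads_kept reads surviving the cleaning steps.
#' @param reads_total reads produced by the sequencer.
#' @return Percentage kept, rounded to 1 decimal place.
#' @examples
#' retention_percent(216895404, 236749964)  # 91.6
#' @export
retention_percent <- function(reads_kept, reads_total) {
  if (reads_total <= 0) stop("reads_total must be > 0")
  if (reads_kept < 0 || reads_kept > reads_total)
    stop("reads_kept must lie in [0, reads_total]")
  round(100 * reads_kept / reads_total, 1)
}

#' Expected fold coverage of a genome
#'
#' Computes the expected sequencing depth `n_reads * read_length /
#' genome_size`, reported as an integer fold value using the ceiling. The
#' ceiling convention is adopted because a partial fold still requires the
#' corresponding sequencing effort; it is the convention under which the
#' standard 125 bp paired-end arithmetic is self-consistent.
#'
#' @param n_reads number of reads.
#' @param read_length read length in bp.
#' @param genome_size genome size in bp.
#' @return Integer fold coverage (X).
#' @examples
#' coverage_estimate(216895404, 125, 486e6)  # 56
#' @export
coverage_estimate <- function(n_reads, read_length, genome_size) {
  if (any(c(n_reads, read_length, genome_size) <= 0))
    stop("all coverage inputs must be positive")
  as.integer(ceiling(n_reads * read_length / genome_size))
}

#' Drop contigs below a minimum length
#'
#' @param contigs a `Biostrings::DNAStringSet`, character vector of
#'   sequences, or numeric vector of contig lengths.
#' @param min_len minimum retained length in bp (default 1000).
#' @return The retained contigs, input order preserved.
#' @export
filter_contigs <- function(contigs, min_len = 1000) {
  lens <- contig_lengths(contigs)
  contigs[lens >= min_len]
}

contig_lengths <- function(contigs) {
  if (is.numeric(contigs)) return(contigs)
  if (is.character(contigs)) return(nchar(contigs))
  if (methods::is(contigs, "XStringSet")) return(Biostrings::width(contigs))
  stop("contigs must be sequences or lengths")
}

#' Assembly N50
#'
#' Length of the shortest contig among the largest contigs that together
#' cover at least half of the total assembly length.
#'
#' @param lengths contig lengths in bp (or sequences; lengths are taken).
#' @return N50 in bp.
#' @examples
#' n50(c(5, 4, 3, 2, 1))  # 4
#' @export
n50 <- function(lengths) {
  lens <- contig_lengths(lengths)
  if (length(lens) == 0) stop("n50 of an empty contig set is undefined")
  lens <- sort(lens, decreasing = TRUE)
  csum <- cumsum(lens)
  lens[which(csum >= sum(lens) / 2)[1]]
}

#' GC percentage of an assembly
#'
#' Percentage of C and G bases over the total assembly length. Ambiguous
#' bases (N) count in the denominator only, so an assembly with unresolved
#' stretches reports a correspondingly lower GC.
#'
#' @param contigs `DNAStringSet` or character vector of sequences.
#' @param digits rounding for the report; the integer default matches how
#'   assembly tables conventionally print GC.
#' @return GC percentage in `[0, 100]`.
#' @export
gc_percent <- function(contigs, digits = 0) {
  if (is.character(contigs)) contigs <- Biostrings::DNAStringSet(contigs)
  if (!methods::is(contigs, "XStringSet")) stop("contigs must be sequences")
  total <- sum(Biostrings::width(contigs))
  if (total == 0) stop("gc_percent of an empty assembly is undefined")
  freq <- Biostrings::alphabetFrequency(contigs, baseOnly = TRUE, collapse = TRUE)
  round(100 * (freq[["C"]] + freq[["G"]]) / total, digits)
}

#' Assembly metrics report
#'
#' Applies the minimum-length contig filter and reports contig count, total
#' size, N50 and GC percentage in one pass.
#'
#' @inheritParams filter_contigs
#' @return A list with `n_contigs`, `total_size`, `n50`, `gc_percent`.
#' @export
assembly_metrics <- function(contigs, min_len = 1000) {
  kept <- filter_contigs(contigs, min_len)
  if (length(kept) == 0) stop("no contigs at or above min_len")
  list(
    n_contigs = length(kept),
    total_size = sum(contig_lengths(kept)),
    n50 = n50(kept),
    gc_percent = gc_percent(kept)
  )
}
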
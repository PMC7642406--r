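# Shared small synthetic cohort, built once per test run.

tiny_config <- function(seed = 42, ...) {
  sim_config(seed = seed,
             chromosome_lengths = c(chr1 = 80000, chr2 = 80000),
             n_genes = 6,
             snp_rate = 0.006, indel_rate = 0.0012, ...)
}

.cohort_cache <- new.env(parent = emptyenv())

shared_cohort <- function() {
  if (!exists("cohort", envir = .cohort_cache)) {
    cfg <- tiny_config()
    genome_obj <- generate_genome(cfg)
    individuals <- generate_individuals(genome_obj, cfg)
    pileups <- generate_rna_pileups(genome_obj, individuals, cfg)
    assign("cohort",
           list(cfg = cfg, genome_obj = genome_obj,
                individuals = individuals, pileups = pileups),
           envir = .cohort_cache)
  }
  get("cohort", envir = .cohort_cache)
}

# minimal single-exon plus-strand gene with known sequence, for codon tests
toy_gene_genome <- function(cds_codons = "GAATATCAT", strand = "+") {
  # layout: 100 bp pad | 10 bp utr5 | ATG cds stop | 10 bp utr3 | pad
  cds <- paste0("ATG", cds_codons, "TAA")
  utr5 <- strrep("C", 10); utr3 <- strrep("G", 10)
  tx <- paste0(utr5, cds, utr3)
  if (strand == "-")
    tx <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(tx)))
  seq <- paste0(strrep("A", 100), tx, strrep("T", 100))
  g0 <- 101L
  L <- nchar(tx)
  iv <- function(s, e) data.frame(start = g0 + s - 1L, end = g0 + e - 1L)
  n5 <- 10L; nc <- nchar(cds); n3 <- 10L
  rel <- list(utr5 = c(1L, n5), cds = c(n5 + 1L, n5 + nc),
              utr3 = c(n5 + nc + 1L, n5 + nc + n3))
  if (strand == "-") {
    rel <- lapply(rel, function(r) c(L - r[2] + 1L, L - r[1] + 1L))
    names(rel) <- c("utr3", "cds", "utr5")[match(names(rel),
                                                 c("utr5", "cds", "utr3"))]
  }
  model <- gene_model("toy", "chrT", strand, g0, g0 + L - 1L,
                      exons = iv(1L, L),
                      cds = iv(rel$cds[1], rel$cds[2]),
                      utr5 = iv(rel$utr5[1], rel$utr5[2]),
                      utr3 = iv(rel$utr3[1], rel$utr3[2]))
  genome <- Biostrings::DNAStringSet(seq)
  names(genome) <- "chrT"
  list(model = model, genome = genome, cds_start = g0 + rel$cds[1] - 1L)
}

# brute-force oracle: full protein translation before/after a variant
translate_with_variant <- function(model, genome, pos, ref, alt) {
  chrom <- as.character(genome[[model$chrom]])
  stopifnot(substr(chrom, pos, pos + nchar(ref) - 1L) == ref)
  mutated <- paste0(substr(chrom, 1, pos - 1L), alt,
                    substr(chrom, pos + nchar(ref), nchar(chrom)))
  shift <- nchar(alt) - nchar(ref)
  cds <- model$cds
  # shift CDS intervals downstream of the edit so they track the new
  # coordinates (variants inside the CDS stretch/shrink their interval)
  adj <- cds
  for (i in seq_len(nrow(adj))) {
    if (cds$start[i] > pos) adj$start[i] <- cds$start[i] + shift
    if (cds$end[i] >= pos) adj$end[i] <- cds$end[i] + shift
  }
  pieces <- vapply(seq_len(nrow(adj)), function(i)
    substr(mutated, adj$start[i], adj$end[i]), character(1))
  s <- Biostrings::DNAString(paste(pieces, collapse = ""))
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  n_keep <- 3L * (length(s) %/% 3L)
  suppressWarnings(as.character(
    Biostrings::translate(Biostrings::subseq(s, 1L, n_keep),
                          no.init.codon = TRUE)))
}

translate_reference <- function(model, genome) {
  as.character(Biostrings::translate(coding_sequence(model, genome),
                                     no.init.codon = TRUE))
}
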
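# two adjacent plus-strand genes for window/precedence checks
two_gene_models <- function() {
  mk <- function(id, start, end, strand = "+") {
    len <- end - start + 1
    cds_len <- 3 * ((len - 20) %/% 3)
    cds_start <- start + 10
    gene_model(id, "chr1", strand, start, end,
               exons = data.frame(start = start, end = end),
               cds = data.frame(start = cds_start,
                                end = cds_start + cds_len - 1),
               utr5 = data.frame(start = start, end = cds_start - 1),
               utr3 = data.frame(start = cds_start + cds_len, end = end))
  }
  list(A = mk("A", 10000, 10999), B = mk("B", 18000, 18999))
}

test_that("context windows are 5 kbp and strand-aware", {
  models <- two_gene_models()
  ctx_at <- function(pos) {
    v <- data.frame(chrom = "chr1", pos = pos)
    assign_context(v, models)
  }
  # 2 kb 5' of gene A start -> upstream of A
  expect_equal(ctx_at(8000)$context, "upstream")
  expect_equal(ctx_at(8000)$gene_id, "A")
  # just outside the 5 kb window -> intergenic
  expect_equal(ctx_at(4999)$context, "intergenic")
  # inside gene features
  expect_equal(ctx_at(10005)$context, "utr5")
  expect_equal(ctx_at(10500)$context, "cds")
  expect_equal(ctx_at(10998)$context, "utr3")
  # between the genes: 3 kb downstream of A and 4 kb upstream of B
  # -> the more relevant upstream label wins
  between <- ctx_at(14000)
  expect_equal(between$context, "upstream")
  expect_equal(between$gene_id, "B")
  # minus-strand gene: upstream lies on the right
  minus <- list(M = gene_model("M", "chr1", "-", 10000, 10999,
                               exons = data.frame(start = 10000, end = 10999),
                               cds = data.frame(start = 10010, end = 10990)))
  v <- data.frame(chrom = "chr1", pos = c(12000, 8000))
  ctx <- assign_context(v, minus)
  expect_equal(ctx$context, c("upstream", "downstream"))
})

test_that("variants on unannotated chromosomes are intergenic with warning", {
  models <- two_gene_models()
  v <- data.frame(chrom = "chrZ", pos = 100)
  expect_warning(ctx <- assign_context(v, models), "without annotation")
  expect_equal(ctx$context, "intergenic")
})

test_that("every variant gets exactly one context and counts are conserved", {
  co <- shared_cohort()
  ctx <- assign_context(co$individuals$WM, co$genome_obj$models)
  expect_equal(nrow(ctx), nrow(co$individuals$WM))
  expect_true(all(ctx$context %in% c("cds", "utr5", "utr3", "intron",
                                     "upstream", "downstream", "intergenic")))
  expect_equal(sum(table(ctx$context)), nrow(co$individuals$WM))
})

test_that("context sizes partition the genome", {
  co <- shared_cohort()
  lens <- vapply(co$genome_obj$genome, length, integer(1))
  sizes <- context_sizes(co$genome_obj$models, lens)
  expect_equal(sum(sizes), sum(lens))
  expect_true(all(sizes >= 0))
})

test_that("codon-level SNP impacts follow the standard genetic code", {
  toy <- toy_gene_genome("GAATATCAT")  # protein: M E Y H *
  g <- toy$genome; m <- toy$model; s <- toy$cds_start
  # GAA -> GAG at the third codon position: Glu -> Glu
  expect_equal(classify_snp_effect(s + 5, "A", "G", m, g), "synonymous")
  # TAT -> TAA: premature stop
  expect_equal(classify_snp_effect(s + 8, "T", "A", m, g), "stop_gained")
  # GAA -> GTA: Glu -> Val
  expect_equal(classify_snp_effect(s + 4, "A", "T", m, g), "non_synonymous")
  # ATG start codon destroyed
  expect_equal(classify_snp_effect(s, "A", "C", m, g), "start_lost")
  # stop codon TAA -> CAA read-through
  expect_equal(classify_snp_effect(s + 12, "T", "C", m, g), "stop_lost")
  expect_error(classify_snp_effect(5, "A", "C", m, g), "outside the CDS")
})

test_that("SNP impacts agree with a full-translation oracle", {
  co <- shared_cohort()
  g <- co$genome_obj
  set.seed(101)
  n_checked <- 0
  chrom_text <- lapply(as.character(g$genome), identity)
  while (n_checked < 500) {
    m <- g$models[[sample(length(g$models), 1)]]
    row <- m$cds[sample(nrow(m$cds), 1), ]
    pos <- sample(row$start:row$end, 1)
    ref <- substr(chrom_text[[m$chrom]], pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    label <- classify_snp_effect(pos, ref, alt, m, g$genome)
    before <- translate_reference(m, g$genome)
    after <- translate_with_variant(m, g$genome, pos, ref, alt)
    off <- cds_offset(m, pos)
    codon_i <- off %/% 3 + 1
    oracle <- if (codon_i == 1 && substr(after, 1, 1) != "M") {
      "start_lost"
    } else if (substr(before, codon_i, codon_i) != "*" &&
               substr(after, codon_i, codon_i) == "*") {
      "stop_gained"
    } else if (substr(before, codon_i, codon_i) == "*" &&
               substr(after, codon_i, codon_i) != "*") {
      "stop_lost"
    } else if (identical(before, after)) "synonymous" else "non_synonymous"
    expect_equal(label, oracle,
                 label = sprintf("%s:%d %s>%s (%s)", m$chrom, pos, ref, alt,
                                 m$strand))
    n_checked <- n_checked + 1
  }
})

test_that("impact labels are invariant under strand reflection", {
  plus <- toy_gene_genome("GAATATCAT", strand = "+")
  minus <- toy_gene_genome("GAATATCAT", strand = "-")
  len <- length(plus$genome[[1]])
  # the same transcript-space substitutions, expressed in each layout
  cases <- list(c(5, "A", "G"), c(8, "T", "A"), c(4, "A", "T"))
  for (cs in cases) {
    off <- as.integer(cs[1])
    pos_plus <- plus$cds_start + off
    # mirror position in the reflected genome; alleles complement
    pos_minus <- len - pos_plus + 1
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    expect_equal(
      classify_snp_effect(pos_plus, cs[2], cs[3], plus$model, plus$genome),
      classify_snp_effect(pos_minus, comp[[cs[2]]], comp[[cs[3]]],
                          minus$model, minus$genome))
  }
})

test_that("indel impacts distinguish frameshift and codon-aligned events", {
  toy <- toy_gene_genome("GAATATCATAAATTT")
  g <- as.character(toy$genome[[1]]); m <- toy$model; s <- toy$cds_start
  sub <- function(a, b) substr(g, a, b)
  # 1-bp deletion: frameshift
  expect_equal(
    classify_indel_effect(s + 3, sub(s + 3, s + 4), sub(s + 3, s + 3), m),
    "frameshift")
  # 3-bp deletion of exactly one codon (codon 2, offsets 3-5)
  expect_equal(
    classify_indel_effect(s + 2, sub(s + 2, s + 5), sub(s + 2, s + 2), m),
    "codon_deletion")
  # 3-bp deletion straddling codons 2 and 3 (offsets 4-6)
  expect_equal(
    classify_indel_effect(s + 3, sub(s + 3, s + 6), sub(s + 3, s + 3), m),
    "codon_change_plus_deletion")
  # 3-bp insertion at a codon boundary (after offset 5)
  expect_equal(
    classify_indel_effect(s + 5, sub(s + 5, s + 5),
                          paste0(sub(s + 5, s + 5), "AAA"), m),
    "codon_insertion")
  # 3-bp insertion mid-codon
  expect_equal(
    classify_indel_effect(s + 4, sub(s + 4, s + 4),
                          paste0(sub(s + 4, s + 4), "AAA"), m),
    "codon_change_plus_insertion")
})

test_that("an 8-bp coding deletion shifts the frame and truncates early", {
  toy <- toy_gene_genome(strrep("GAATATCAT", 8))
  g <- as.character(toy$genome[[1]]); m <- toy$model; s <- toy$cds_start
  ref <- substr(g, s + 2, s + 10)   # anchor + 8 deleted bases
  alt <- substr(g, s + 2, s + 2)
  expect_equal(classify_indel_effect(s + 2, ref, alt, m), "frameshift")
  after <- translate_with_variant(m, toy$genome, s + 2, ref, alt)
  before <- translate_reference(m, toy$genome)
  stop_at <- regexpr("\\*", after)[1]
  expect_true(stop_at > 0 && stop_at < nchar(before))
})

test_that("indel alleles are left-normalized before classification", {
  toy <- toy_gene_genome("GAATATCAT")
  m <- toy$model; s <- toy$cds_start
  g <- as.character(toy$genome[[1]])
  # padded representation of the same 1-bp deletion
  raw_ref <- substr(g, s + 3, s + 6)
  raw_alt <- paste0(substr(g, s + 3, s + 3), substr(g, s + 5, s + 6))
  expect_equal(classify_indel_effect(s + 3, raw_ref, raw_alt, m),
               "frameshift")
})
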
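test_that("RPKM follows the reads-per-kilobase-per-million formula", {
  expect_equal(rpkm(1, 1000, 1e6), 1.0)
  expect_equal(rpkm(0, 1000, 1e6), 0.0)
  expect_equal(rpkm(250, 2000, 5e6), 25.0)
  expect_error(rpkm(10, 0, 1e6), "positive")
  expect_error(rpkm(10, 1000, 0), "positive")
})

prefilter_row <- function(dist_to_end = 500, ref_ambiguous = FALSE,
                          copy_number = 1, min_allele_quality = 30,
                          min_allele_reads = 10, variant_frequency = 0.4,
                          coverage = 50) {
  data.frame(dist_to_end = dist_to_end, ref_ambiguous = ref_ambiguous,
             copy_number = copy_number,
             min_allele_quality = min_allele_quality,
             min_allele_reads = min_allele_reads,
             variant_frequency = variant_frequency, coverage = coverage)
}

test_that("transcriptome prefilter discards calls with the first failing rule", {
  keep <- rna_variant_prefilter(prefilter_row())
  expect_true(keep$keep)
  expect_equal(keep$reason, "")
  near_end <- rna_variant_prefilter(prefilter_row(dist_to_end = 30))
  expect_false(near_end$keep)
  expect_equal(near_end$reason, "end_proximity")
  rare <- rna_variant_prefilter(prefilter_row(variant_frequency = 0.10))
  expect_equal(rare$reason, "variant_frequency")
  edge <- rna_variant_prefilter(prefilter_row(coverage = 4,
                                              variant_frequency = 0.2))
  expect_true(edge$keep)   # coverage 4 and frequency 15%+ are admissible
  shallow <- rna_variant_prefilter(prefilter_row(coverage = 3))
  expect_equal(shallow$reason, "coverage")
  multi <- rna_variant_prefilter(
    prefilter_row(dist_to_end = 10, copy_number = 5))
  expect_equal(multi$reason, "end_proximity")  # first rule wins
  amb <- rna_variant_prefilter(prefilter_row(ref_ambiguous = TRUE))
  expect_equal(amb$reason, "ambiguous_reference")
  weak <- rna_variant_prefilter(prefilter_row(min_allele_reads = 1))
  expect_equal(weak$reason, "allele_support")
  lowq <- rna_variant_prefilter(prefilter_row(min_allele_quality = 19))
  expect_equal(lowq$reason, "allele_quality")
})

test_that("allele profiles apply boundary-inclusive 10% and 90% rules", {
  p <- allele_profile(list(A = 9, G = 1))
  expect_setequal(names(p$alleles), c("A", "G"))  # 10% exactly retained
  expect_equal(p$zygosity, "homozygous")          # 90% exactly homozygous
  p2 <- allele_profile(list(A = 95, G = 5))
  expect_equal(names(p2$alleles), "A")
  expect_equal(p2$zygosity, "homozygous")
  p3 <- allele_profile(list(A = 50, G = 50))
  expect_setequal(names(p3$alleles), c("A", "G"))
  expect_equal(p3$zygosity, "heterozygous")
  p4 <- allele_profile(list(A = 89, G = 11))
  expect_equal(p4$zygosity, "heterozygous")
  expect_error(allele_profile(list(A = 0, C = 0)), "positive depth")
})

test_that("the site gate needs simultaneous coverage, expression, no indels", {
  ok <- site_passes_filters(10, 50, rep(2, 6))
  expect_true(ok$pass)
  dna_low <- site_passes_filters(4, 50, rep(2, 6))
  expect_false(dna_low$pass)
  expect_equal(dna_low$reasons, "dna_coverage")
  expr_low <- site_passes_filters(10, 50, c(rep(2, 5), 0.5))
  expect_equal(expr_low$reasons, "expression")
  indel <- site_passes_filters(10, 50, rep(2, 6), has_indel = TRUE)
  expect_equal(indel$reasons, "indel_evidence")
  expect_error(site_passes_filters(10, 50, rep(2, 5)), "all 6 samples")
  boundary <- site_passes_filters(5, 5, rep(1, 6))
  expect_true(boundary$pass)
})

test_that("editing calls require an RNA allele unsupported by the genome", {
  hom_t <- allele_profile(list(T = 40))
  mixed <- allele_profile(list(T = 60, A = 40))
  call <- call_editing(hom_t, mixed)
  expect_equal(call$mode, "two_variant")
  expect_equal(call$from_base, "T")
  expect_equal(call$to_base, "A")
  hom_c <- allele_profile(list(C = 30))
  all_t <- allele_profile(list(T = 50))
  full <- call_editing(hom_c, all_t)
  expect_equal(full$mode, "full_edit")
  expect_equal(full$to_base, "T")
  het_ag <- allele_profile(list(A = 25, G = 25))
  g_only <- allele_profile(list(G = 50))
  expect_equal(call_editing(het_ag, g_only)$mode, "none")
})

test_that("strict mode requires zero genomic reads of the edited base", {
  # 8% genomic support: below the 10% retention threshold but nonzero
  dna <- allele_profile(list(T = 92, A = 8))
  rna <- allele_profile(list(T = 55, A = 45))
  lax <- call_editing(dna, rna)
  expect_equal(lax$mode, "two_variant")
  strict <- call_editing(dna, rna, dna_counts = list(T = 92, A = 8, C = 0,
                                                     G = 0, del = 0, ins = 0),
                         strict = TRUE)
  expect_equal(strict$mode, "none")
})

test_that("raising the support threshold never adds editing calls", {
  co <- shared_cohort()
  p <- co$pileups
  expr <- expression_table(p$gene_counts, co$genome_obj$models,
                           p$library_sizes)
  sg <- data.frame(chrom = p$rna_pileups$chrom, pos = p$rna_pileups$pos)
  sg <- unique(sg)
  ctx <- assign_context(sg, co$genome_obj$models, window = 0)
  sg$gene <- ctx$gene_id
  n_calls <- vapply(c(0.05, 0.10, 0.25, 0.45), function(sf) {
    calls <- detect_editing(p$dna_pileups, p$rna_pileups, expr, sg,
                            support_frac = sf)
    sum(!is.na(calls$mode) & calls$mode != "none")
  }, numeric(1))
  expect_true(all(diff(n_calls) <= 0))
})

test_that("every pileup row yields a pass or a machine-readable reason", {
  co <- shared_cohort()
  res <- run_editing(co$pileups, co$genome_obj)
  calls <- res$calls
  expect_equal(nrow(calls), nrow(co$pileups$rna_pileups))
  expect_true(all(calls$pass | calls$reasons != ""))
  expect_equal(sum(calls$pass) + sum(!calls$pass), nrow(calls))
})

test_that("planted editing events are recovered exactly on the clean cohort", {
  co <- shared_cohort()
  res <- run_editing(co$pileups, co$genome_obj)
  ev <- res$summary$calls
  truth_keys <- paste(co$pileups$truth$chrom, co$pileups$truth$pos,
                      co$pileups$truth$sample)
  call_keys <- paste(ev$chrom, ev$pos, ev$sample)
  expect_setequal(call_keys, truth_keys)
  merged <- merge(ev, co$pileups$truth,
                  by.x = c("chrom", "pos", "sample"),
                  by.y = c("chrom", "pos", "sample"))
  expect_equal(merged$mode.x, merged$mode.y)
  expect_equal(merged$to_base.x, merged$to_base.y)
  expect_equal(merged$from_base.x, merged$from_base.y)
})

test_that("editing summaries split CDS from non-CDS events per gene", {
  co <- shared_cohort()
  res <- run_editing(co$pileups, co$genome_obj,
                     region = list(chrom = "chr1", start = 1, end = 80000))
  pg <- res$summary$per_gene
  expect_equal(sum(pg$events), nrow(co$pileups$truth))
  expect_equal(pg$events, pg$cds_events + pg$non_cds_events)
  reg <- res$summary$region
  expect_equal(reg$inside + reg$outside, nrow(co$pileups$truth))
  empty <- annotate_editing(
    data.frame(chrom = character(0), pos = integer(0), sample = character(0),
               gene = character(0), pass = logical(0), reasons = character(0),
               mode = character(0), from_base = character(0),
               to_base = character(0), stringsAsFactors = FALSE),
    co$genome_obj$models, co$genome_obj$genome)
  expect_equal(nrow(empty$per_gene), 0)
})
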
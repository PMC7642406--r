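test_that("generated genes have well-formed coding sequences", {
  co <- shared_cohort()
  g <- co$genome_obj
  expect_equal(length(g$models), co$cfg$n_genes)
  for (m in g$models) {
    expect_equal(m$cds_len %% 3, 0)
    cds <- coding_sequence(m, g$genome)
    expect_equal(as.character(Biostrings::subseq(cds, 1, 3)), "ATG")
    expect_true(as.character(
      Biostrings::subseq(cds, length(cds) - 2, length(cds))) %in%
        c("TAA", "TAG", "TGA"))
    prot <- as.character(Biostrings::translate(cds))
    # exactly one stop, at the end
    expect_equal(as.integer(gregexpr("\\*", prot)[[1]]), nchar(prot))
    # exons cover utr5 + cds + utr3 exactly
    expect_equal(sum(m$exons$end - m$exons$start + 1),
                 sum(rbind(m$cds, m$utr5, m$utr3)$end -
                       rbind(m$cds, m$utr5, m$utr3)$start + 1))
  }
  # genes separated by >= 12 kbp within a chromosome
  for (ch in unique(vapply(g$models, `[[`, character(1), "chrom"))) {
    ms <- Filter(function(m) m$chrom == ch, g$models)
    if (length(ms) < 2) next
    spans <- do.call(rbind, lapply(ms, function(m) c(m$start, m$end)))
    spans <- spans[order(spans[, 1]), , drop = FALSE]
    gaps <- spans[-1, 1] - spans[-nrow(spans), 2]
    expect_true(all(gaps >= 12000))
  }
})

test_that("the same seed reproduces the cohort byte for byte", {
  cfg <- tiny_config(seed = 9)
  d1 <- file.path(tempdir(), "sim1"); d2 <- file.path(tempdir(), "sim2")
  run_simulate(cfg, d1)
  run_simulate(cfg, d2)
  for (f in c("reference.fa", "annotation.gff3", "dna_pileups.tsv",
              "rna_pileups.tsv", "gene_counts.tsv", "truth.json")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  # VCFs are compressed; compare parsed content
  v1 <- read_variants(file.path(d1, "WF.vcf.gz"))
  v2 <- read_variants(file.path(d2, "WF.vcf.gz"))
  expect_identical(v1, v2)
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("a genome without genes is valid", {
  cfg <- sim_config(seed = 5, chromosome_lengths = c(chr1 = 20000),
                    n_genes = 0)
  g <- generate_genome(cfg)
  expect_equal(length(g$genome[[1]]), 20000)
  expect_length(g$models, 0)
})

test_that("infeasible gene placement raises an explicit error", {
  cfg <- sim_config(seed = 5, chromosome_lengths = c(chr1 = 15000),
                    n_genes = 10)
  expect_error(generate_genome(cfg), "cannot place gene")
})

test_that("GFF3 round trip reproduces the gene models", {
  co <- shared_cohort()
  path <- file.path(tempdir(), "models.gff3")
  write_gene_models_gff3(co$genome_obj$models, path)
  back <- read_gene_models(path)
  expect_setequal(names(back), names(co$genome_obj$models))
  for (nm in names(back)) {
    a <- co$genome_obj$models[[nm]]; b <- back[[nm]]
    expect_equal(b$strand, a$strand)
    expect_equal(b$cds, a$cds)
    expect_equal(b$exons, a$exons)
    expect_equal(b$utr5, a$utr5)
    expect_equal(b$utr3, a$utr3)
  }
})

test_that("planted genotype and sharing structure is recovered", {
  co <- shared_cohort()
  ind <- co$individuals
  # het fraction within 3 SE of the target
  for (v in list(ind$WF, ind$WM)) {
    het <- mean(v$genotype_class != "hom_alt")
    se <- sqrt(co$cfg$het_fraction * (1 - co$cfg$het_fraction) / nrow(v))
    expect_lt(abs(het - co$cfg$het_fraction), 3 * se)
  }
  # shared fraction of the union within 3 SE
  se_sets <- shared_exclusive(ind$WF, ind$WM)
  union_n <- se_sets$shared + se_sets$only_a + se_sets$only_b
  se <- sqrt(0.25 / union_n)
  expect_lt(abs(se_sets$shared / union_n - co$cfg$shared_fraction), 3 * se)
  # truth ledger matches the call sets exactly
  expect_equal(nrow(ind$truth), nrow(ind$WF) + nrow(ind$WM))
  expect_identical(ind$truth[ind$truth$individual == "WF", "pos"], ind$WF$pos)
  # SNP and indel positions never collide within an individual
  for (v in list(ind$WF, ind$WM))
    expect_equal(anyDuplicated(paste(v$chrom, v$pos)), 0)
})

test_that("het_fraction = 1 plants no homozygous records", {
  cfg <- tiny_config(seed = 3, het_fraction = 1)
  g <- generate_genome(cfg)
  ind <- generate_individuals(g, cfg)
  expect_false(any(ind$WF$genotype_class == "hom_alt"))
  expect_false(any(ind$WM$genotype_class == "hom_alt"))
})

test_that("RNA pileups carry planted edits at the planted fraction", {
  co <- shared_cohort()
  p <- co$pileups
  for (i in seq_len(nrow(p$truth))) {
    ev <- p$truth[i, ]
    r <- p$rna_pileups[p$rna_pileups$chrom == ev$chrom &
                         p$rna_pileups$pos == ev$pos &
                         p$rna_pileups$sample == ev$sample, ]
    expect_equal(nrow(r), 1)
    depth <- sum(r[, c("A", "C", "G", "T")])
    k <- r[[ev$to_base]]
    if (ev$mode == "full_edit") {
      expect_lt(r[[ev$from_base]] / depth, 0.1)
    } else {
      se <- sqrt(ev$fraction * (1 - ev$fraction) * depth)
      expect_lt(abs(k - ev$fraction * depth), 3 * se + 1)
    }
    # DNA pileups contain only the genomic allele
    d <- p$dna_pileups[p$dna_pileups$chrom == ev$chrom &
                         p$dna_pileups$pos == ev$pos, ]
    expect_true(all(d[[ev$to_base]] == 0))
  }
})

test_that("unexpressed genes fall below the RPKM floor", {
  co <- shared_cohort()
  expr <- expression_table(co$pileups$gene_counts, co$genome_obj$models,
                           co$pileups$library_sizes)
  last_gene <- utils::tail(names(co$genome_obj$models), 1)
  expect_true(any(expr$rpkm[expr$gene_id == last_gene] < 1))
  others <- expr$rpkm[expr$gene_id != last_gene]
  expect_true(all(others >= 1))
})

test_that("editing events cannot be placed outside the transcript", {
  co <- shared_cohort()
  cfg <- co$cfg
  m <- co$genome_obj$models[[1]]
  cfg$editing_sites <- data.frame(
    gene = m$gene_id, tx_offset = sum(m$exons$end - m$exons$start + 1) + 50,
    to_base = "A", fraction = 0.5, samples = "WF_B",
    stringsAsFactors = FALSE)
  expect_error(
    generate_rna_pileups(co$genome_obj, co$individuals, cfg),
    "outside transcript")
})
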
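#' Simulation configuration for a synthetic resequencing cohort
#'
#' Defines a small multi-chromosome diploid genome, two unrelated
#' individuals with controlled variant structure, and matched DNA/RNA
#' pileups with planted RNA-editing events. The defaults mirror the study
#' design the package targets: two individuals (WF, WM), RNA from three
#' inflorescence developmental stages (B, D, H) per individual, roughly
#' half of the variants shared between the individuals, a transition/
#' transversion ratio near 2 and a heterozygous fraction near 0.65
#' (het/hom about 1.8).
#'
#' @param seed integer seed; identical configs give identical cohorts.
#' @param chromosome_lengths named bp lengths of the chromosomes.
#' @param n_genes number of genes to place.
#' @param gene_structure list of ranges: `n_exons`, `exon_min_bp`,
#'   `cds_codons`, `intron_bp`, `utr5_bp`, `utr3_bp`.
#' @param snp_rate SNP events per bp in the union of the two individuals.
#' @param indel_rate indel events per bp in the union.
#' @param target_titv planted transition/transversion ratio.
#' @param het_fraction fraction of planted variants that are heterozygous.
#' @param het_alt_alt_fraction fraction of heterozygous records with two
#'   non-reference alleles (the 1/2 class); the default reproduces a
#'   0/1 : 1/1 : 1/2 mix of roughly 60 : 35 : 5.
#' @param shared_fraction fraction of union variants planted in both
#'   individuals (shared variants share alleles and genotype class, so the
#'   (chrom, pos, ref, alt) key is identical in both call sets).
#' @param editing_sites optional `data.frame(gene, tx_offset, to_base,
#'   fraction, samples)` of planted editing events (`tx_offset` is 1-based
#'   in the spliced transcript; `samples` comma-separated RNA sample ids;
#'   `fraction` in (0, 1], 1 = full edit). `NULL` auto-places
#'   `n_edit_two_variant` partial and `n_edit_full` complete events.
#' @param n_edit_two_variant,n_edit_full number of auto-placed events.
#' @param edit_fraction edited-read fraction for auto-placed two-variant
#'   events.
#' @param rna_depth_mean,dna_depth_mean mean pileup depths (reads/site).
#' @param rpkm_floor minimum expression of expressed genes (RPKM).
#' @param n_unexpressed number of genes deliberately left below the RPKM
#'   gate in at least one sample.
#' @param library_size total mapped reads per RNA sample (RPKM
#'   denominator).
#' @return A `sim_config` list, validated.
#' @export
sim_config <- function(seed = 1,
                       chromosome_lengths = c(chr1 = 120000, chr2 = 120000,
                                              chr3 = 100000),
                       n_genes = 9,
                       gene_structure = list(n_exons = c(1, 3),
                                             exon_min_bp = 40,
                                             cds_codons = c(60, 150),
                                             intron_bp = c(80, 300),
                                             utr5_bp = c(60, 120),
                                             utr3_bp = c(80, 200)),
                       snp_rate = 0.012, indel_rate = 0.0024,
                       target_titv = 2.0,
                       het_fraction = 0.65,
                       het_alt_alt_fraction = 5 / 65,
                       shared_fraction = 0.5,
                       editing_sites = NULL,
                       n_edit_two_variant = 6, n_edit_full = 2,
                       edit_fraction = 0.4,
                       rna_depth_mean = 60, dna_depth_mean = 40,
                       rpkm_floor = 1, n_unexpressed = 1,
                       library_size = 2e6) {
  cfg <- as.list(environment())
  rates <- c(snp_rate, indel_rate, het_fraction, het_alt_alt_fraction,
             shared_fraction)
  if (any(rates < 0 | rates > 1))
    stop("rates and fractions must lie in [0, 1]")
  if (target_titv <= 0) stop("target_titv must be positive")
  if (edit_fraction <= 0 || edit_fraction > 1)
    stop("edit_fraction must lie in (0, 1]")
  if (is.null(names(chromosome_lengths)))
    names(cfg$chromosome_lengths) <-
      paste0("chr", seq_along(chromosome_lengths))
  class(cfg) <- "sim_config"
  cfg
}

rna_samples <- function()
  c("WF_B", "WF_D", "WF_H", "WM_B", "WM_D", "WM_H")

dna_bases <- c("A", "C", "G", "T")
stop_codons <- c("TAA", "TAG", "TGA")

random_seq <- function(n) paste(sample(dna_bases, n, replace = TRUE),
                                collapse = "")

random_cds <- function(n_codons) {
  all_codons <- as.vector(outer(outer(dna_bases, dna_bases, paste0),
                                dna_bases, paste0))
  safe <- setdiff(all_codons, stop_codons)
  paste0("ATG",
         paste(sample(safe, n_codons - 2, replace = TRUE), collapse = ""),
         sample(stop_codons, 1))
}

# split total into n parts, each >= min_part
split_lengths <- function(total, n, min_part) {
  if (n == 1) return(total)
  slack <- total - n * min_part
  if (slack < 0) stop("cannot split ", total, " into ", n, " parts")
  cuts <- sort(sample(0:slack, n - 1, replace = TRUE))
  diff(c(0, cuts, slack)) + min_part
}

#' Generate a reference genome with gene models
#'
#' Builds random chromosome sequences and places stranded protein-coding
#' genes (ATG start, in-frame stop, CDS length a multiple of 3, optional
#' introns and UTRs), with at least 12 kbp between genes so that 5 kbp
#' context windows of adjacent genes need not overlap.
#'
#' @param config a [sim_config()].
#' @return List with `genome` (named `DNAStringSet`), `models` (named list
#'   of [gene_model()]) and the `config`.
#' @export
generate_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gs <- config$gene_structure
  lens <- config$chromosome_lengths
  chroms <- lapply(lens, random_seq)
  models <- list()
  margin <- 3000L; spacing <- 12000L
  cursors <- stats::setNames(rep(margin, length(lens)), names(lens))
  chrom_i <- 0L
  for (g in seq_len(config$n_genes)) {
    gid <- sprintf("gene%02d", g)
    built <- build_gene_parts(gs)
    placed <- FALSE
    for (try in seq_along(lens)) {
      chrom_i <- chrom_i %% length(lens) + 1L
      ch <- names(lens)[chrom_i]
      g0 <- cursors[[ch]]
      if (g0 + built$len + margin <= lens[[ch]]) {
        strand <- sample(c("+", "-"), 1)
        model <- realize_gene(gid, ch, strand, g0, built)
        seq_chars <- built$seq
        if (strand == "-")
          seq_chars <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(seq_chars)))
        substr(chroms[[ch]], g0, g0 + built$len - 1) <- seq_chars
        models[[gid]] <- model
        cursors[[ch]] <- g0 + built$len + spacing
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("cannot place gene ", gid,
           ": chromosomes too short for the requested gene count")
  }
  genome <- Biostrings::DNAStringSet(unlist(chroms))
  names(genome) <- names(lens)
  list(genome = genome, models = models, config = config)
}

# draw transcript structure and sequence; coordinates relative to a
# plus-strand layout starting at 1
build_gene_parts <- function(gs) {
  u5 <- sample(gs$utr5_bp[1]:gs$utr5_bp[2], 1)
  u3 <- sample(gs$utr3_bp[1]:gs$utr3_bp[2], 1)
  n_codons <- sample(gs$cds_codons[1]:gs$cds_codons[2], 1)
  cds_len <- 3L * n_codons
  tx_len <- u5 + cds_len + u3
  n_ex <- sample(gs$n_exons[1]:gs$n_exons[2], 1)
  exon_tx <- split_lengths(tx_len, n_ex, gs$exon_min_bp)
  introns <- if (n_ex > 1)
    sample(gs$intron_bp[1]:gs$intron_bp[2], n_ex - 1, replace = TRUE)
  else integer(0)
  tx_seq <- paste0(random_seq(u5), random_cds(n_codons), random_seq(u3))
  # relative genomic exon coordinates (sense layout)
  rel_start <- integer(n_ex); rel_end <- integer(n_ex)
  tx_start <- integer(n_ex); tx_end <- integer(n_ex)
  cursor_g <- 1L; cursor_t <- 1L
  pieces <- character(0)
  for (j in seq_len(n_ex)) {
    rel_start[j] <- cursor_g
    rel_end[j] <- cursor_g + exon_tx[j] - 1L
    tx_start[j] <- cursor_t
    tx_end[j] <- cursor_t + exon_tx[j] - 1L
    pieces <- c(pieces, substr(tx_seq, tx_start[j], tx_end[j]))
    cursor_g <- rel_end[j] + 1L
    cursor_t <- tx_end[j] + 1L
    if (j < n_ex) {
      pieces <- c(pieces, random_seq(introns[j]))
      cursor_g <- cursor_g + introns[j]
    }
  }
  list(len = cursor_g - 1L, seq = paste(pieces, collapse = ""),
       u5 = u5, cds_len = cds_len, u3 = u3, tx_len = tx_len,
       exon_rel = data.frame(start = rel_start, end = rel_end),
       exon_tx = data.frame(start = tx_start, end = tx_end))
}

# turn the sense-layout parts into a gene_model at g0 on the given strand
realize_gene <- function(gid, chrom, strand, g0, built) {
  L <- built$len
  abs_iv <- function(rel) {
    if (nrow(rel) == 0) return(empty_intervals())
    if (strand == "-") {
      rel <- data.frame(start = L - rel$end + 1L, end = L - rel$start + 1L)
    }
    sort_intervals(data.frame(start = g0 - 1L + rel$start,
                              end = g0 - 1L + rel$end))
  }
  feature_rel <- function(f_start, f_end) {
    if (f_end < f_start) return(empty_intervals())
    out <- list()
    for (j in seq_len(nrow(built$exon_tx))) {
      s <- max(f_start, built$exon_tx$start[j])
      e <- min(f_end, built$exon_tx$end[j])
      if (s <= e) {
        off <- built$exon_rel$start[j] - built$exon_tx$start[j]
        out[[length(out) + 1]] <- data.frame(start = s + off, end = e + off)
      }
    }
    if (length(out) == 0) empty_intervals() else do.call(rbind, out)
  }
  u5_end <- built$u5
  cds_end <- built$u5 + built$cds_len
  gene_model(gid, chrom, strand, g0, g0 + L - 1L,
             exons = abs_iv(built$exon_rel),
             cds = abs_iv(feature_rel(u5_end + 1L, cds_end)),
             utr5 = abs_iv(feature_rel(1L, u5_end)),
             utr3 = abs_iv(feature_rel(cds_end + 1L, built$tx_len)))
}

#' Genomic position of a transcript offset
#'
#' @param model a [gene_model()].
#' @param t 1-based offset in the spliced transcript (transcription
#'   order).
#' @return Genomic position (1-based).
#' @export
tx_to_genomic <- function(model, t) {
  ex <- model$exons
  if (model$strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  widths <- ex$end - ex$start + 1L
  if (t < 1 || t > sum(widths))
    stop("transcript offset ", t, " outside transcript of ", model$gene_id)
  cum <- cumsum(widths)
  j <- which(cum >= t)[1]
  within <- t - (if (j > 1) cum[j - 1] else 0L) - 1L
  if (model$strand == "+") ex$start[j] + within else ex$end[j] - within
}

#' Generate the two individuals' variant sets
#'
#' Plants a union of SNP and indel positions uniformly over the genome,
#' assigns each union variant to both individuals with probability
#' `shared_fraction` (otherwise to one at random), draws substitution
#' types at the target transition/transversion ratio and genotype classes
#' at the target heterozygous fraction, and attaches nominal passing
#' quality metrics. SNP and indel positions never collide within an
#' individual.
#'
#' @param genome_obj from [generate_genome()].
#' @param config a [sim_config()]; defaults to the genome's.
#' @return List with variant tables `WF` and `WM` and a `truth` ledger
#'   `data.frame(individual, chrom, pos, ref, alt, genotype_class, kind)`.
#' @export
generate_individuals <- function(genome_obj, config = genome_obj$config) {
  set.seed(config$seed + 1L)
  genome <- genome_obj$genome
  lens <- config$chromosome_lengths
  genome_size <- sum(lens)
  n_snp <- round(config$snp_rate * genome_size)
  n_indel <- round(config$indel_rate * genome_size)
  # joint position draw so SNPs and indels never collide
  chrom_of <- rep(names(lens), lens)
  offset_of <- unlist(lapply(lens, seq_len), use.names = FALSE)
  usable <- offset_of <= unname(lens[chrom_of]) - 5  # room for deletions
  idx <- sample(which(usable), n_snp + n_indel)
  is_snp <- c(rep(TRUE, n_snp), rep(FALSE, n_indel))
  chrom <- chrom_of[idx]; pos <- offset_of[idx]
  chrom_text <- as.character(genome)
  ref_base <- substring(chrom_text[chrom], pos, pos)
  # Per-allele transition probability. Heterozygous 1/2 records carry a
  # second non-reference allele, and when the first alternate is the
  # transition partner the second is forced to be a transversion; the
  # transition probability is therefore solved so that the expected
  # allele-level Ti/Tv equals the target given the 1/2 class fraction q:
  #   p + q * (1 - p) * p = (1 + q) * R / (1 + R)
  q <- config$het_fraction * config$het_alt_alt_fraction
  tgt <- (1 + q) * config$target_titv / (1 + config$target_titv)
  p_ti <- if (q > 0)
    ((1 + q) - sqrt((1 + q)^2 - 4 * q * tgt)) / (2 * q)
  else tgt
  transition_of <- c(A = "G", G = "A", C = "T", T = "C")
  draw_alt_snp <- function(ref) {
    if (stats::runif(1) < p_ti) transition_of[[ref]]
    else sample(setdiff(dna_bases, c(ref, transition_of[[ref]])), 1)
  }
  ref <- character(length(idx)); alt1 <- character(length(idx))
  for (i in seq_along(idx)) {
    if (is_snp[i]) {
      ref[i] <- ref_base[i]
      alt1[i] <- draw_alt_snp(ref_base[i])
    } else if (stats::runif(1) < 0.5) {  # insertion after the anchor base
      ref[i] <- ref_base[i]
      alt1[i] <- paste0(ref_base[i], random_seq(sample(1:3, 1)))
    } else {                             # deletion anchored at the base
      del_len <- sample(1:3, 1)
      ref[i] <- substring(chrom_text[chrom[i]], pos[i], pos[i] + del_len)
      alt1[i] <- ref_base[i]
    }
  }
  # genotype class and second alt, drawn once per union variant so that
  # shared variants carry identical keys in both call sets
  gt_class <- ifelse(stats::runif(length(idx)) < config$het_fraction,
                     ifelse(stats::runif(length(idx)) <
                              config$het_alt_alt_fraction,
                            "het_alt_alt", "het_ref_alt"),
                     "hom_alt")
  gt_class[!is_snp & gt_class == "het_alt_alt"] <- "het_ref_alt"
  alt <- alt1
  for (i in which(gt_class == "het_alt_alt")) {
    partner <- transition_of[[ref[i]]]
    pool <- setdiff(dna_bases, c(ref[i], alt1[i]))
    alt2 <- if (partner %in% pool && stats::runif(1) < p_ti) partner
    else sample(setdiff(pool, partner), 1)
    alt[i] <- paste(alt1[i], alt2, sep = ",")
  }
  gt <- c(het_ref_alt = "0/1", hom_alt = "1/1", het_alt_alt = "1/2")[gt_class]
  shared <- stats::runif(length(idx)) < config$shared_fraction
  to_wf <- shared | stats::runif(length(idx)) < 0.5
  to_wm <- shared | !to_wf
  build_set <- function(take) {
    n <- sum(take)
    df <- data.frame(chrom = chrom[take], pos = pos[take], ref = ref[take],
                     alt = alt[take], gt = unname(gt[take]),
                     genotype_class = unname(gt_class[take]),
                     kind = ifelse(is_snp[take], "snp", "indel"),
                     stringsAsFactors = FALSE)
    df$QD <- round(stats::runif(n, 10, 30), 2)
    df$FS <- round(stats::runif(n, 0, 10), 2)
    df$MQRS <- round(stats::runif(n, -2, 2), 2)
    df$HS <- round(stats::runif(n, 0, 5), 2)
    df$RPRS <- round(stats::runif(n, -2, 2), 2)
    df$DP <- 21L + stats::rpois(n, config$dna_depth_mean)
    df$filter_status <- ""
    df$flag <- ""
    df <- df[order(match(df$chrom, names(lens)), df$pos), , drop = FALSE]
    rownames(df) <- NULL
    df
  }
  wf <- build_set(to_wf); wm <- build_set(to_wm)
  truth <- rbind(
    data.frame(individual = "WF", wf[, c("chrom", "pos", "ref", "alt",
                                         "genotype_class", "kind")],
               stringsAsFactors = FALSE),
    data.frame(individual = "WM", wm[, c("chrom", "pos", "ref", "alt",
                                         "genotype_class", "kind")],
               stringsAsFactors = FALSE))
  list(WF = wf, WM = wm, truth = truth)
}

#' Generate matched DNA and RNA pileups with planted editing
#'
#' Plants RNA-editing events at exonic transcript offsets (explicit via
#' `config$editing_sites` or auto-placed, avoiding planted DNA variant
#' positions), then simulates per-site base counts: DNA pileups carry only
#' the genomic alleles of each individual; RNA pileups carry the edited
#' base at the planted fraction (binomial sampling) in the designated
#' samples. Per-gene read counts are drawn so expressed genes exceed the
#' RPKM floor in every sample while `n_unexpressed` genes fall below it.
#' Site depths are Poisson around the configured means.
#'
#' @param genome_obj from [generate_genome()].
#' @param individuals from [generate_individuals()] (their truth ledger is
#'   used to keep editing sites clear of DNA variants).
#' @param config a [sim_config()].
#' @param n_background_sites extra non-edited exonic sites per gene, for
#'   specificity checks.
#' @return List: `dna_pileups`, `rna_pileups` (both
#'   `data.frame(chrom, pos, sample, A, C, G, T, del, ins)`),
#'   `gene_counts` (`gene_id`, `sample`, `reads`), `library_sizes`
#'   (named vector), `truth` (`data.frame(chrom, pos, gene, sample,
#'   from_base, to_base, fraction, mode)`).
#' @export
generate_rna_pileups <- function(genome_obj, individuals,
                                 config = genome_obj$config,
                                 n_background_sites = 3) {
  set.seed(config$seed + 2L)
  genome <- genome_obj$genome
  models <- genome_obj$models
  samples <- rna_samples()
  variant_pos <- paste(individuals$truth$chrom, individuals$truth$pos)
  edits <- config$editing_sites
  expressed <- names(models)
  unexpressed <- character(0)
  if (config$n_unexpressed > 0 && length(models) > config$n_unexpressed) {
    unexpressed <- utils::tail(names(models), config$n_unexpressed)
    expressed <- setdiff(names(models), unexpressed)
  }
  if (is.null(edits)) {
    n_events <- config$n_edit_two_variant + config$n_edit_full
    if (length(expressed) == 0) stop("no expressed genes to edit")
    host <- sample(expressed, n_events, replace = TRUE)
    used <- character(0)
    edits <- do.call(rbind, lapply(seq_len(n_events), function(i) {
      m <- models[[host[i]]]
      tx_len <- interval_bp(m$exons)
      for (attempt in 1:200) {
        t <- sample(tx_len, 1)
        if (paste(host[i], t) %in% used) next
        gpos <- tx_to_genomic(m, t)
        if (!(paste(m$chrom, gpos) %in% variant_pos)) {
          used <<- c(used, paste(host[i], t))
          return(data.frame(gene = host[i], tx_offset = t,
                            to_base = NA_character_,
                            fraction = if (i <= config$n_edit_two_variant)
                              config$edit_fraction else 1.0,
                            samples = sample(samples, 1),
                            stringsAsFactors = FALSE))
        }
      }
      stop("could not place an editing site clear of DNA variants")
    }))
  }
  # resolve genomic coordinates and from/to bases
  truth <- do.call(rbind, lapply(seq_len(nrow(edits)), function(i) {
    e <- edits[i, ]
    m <- models[[e$gene]]
    if (is.null(m)) stop("editing site refers to unknown gene ", e$gene)
    gpos <- tx_to_genomic(m, e$tx_offset)  # errors if outside the exons
    from <- as.character(Biostrings::subseq(genome[[m$chrom]], gpos, gpos))
    to <- e$to_base
    if (is.na(to) || is.null(to)) to <- sample(setdiff(dna_bases, from), 1)
    if (to == from) stop("editing event must change the base")
    smp <- strsplit(e$samples, ",", fixed = TRUE)[[1]]
    if (!all(smp %in% samples)) stop("unknown RNA sample in editing config")
    data.frame(chrom = m$chrom, pos = gpos, gene = e$gene, sample = smp,
               from_base = from, to_base = to, fraction = e$fraction,
               mode = if (e$fraction >= 1) "full_edit" else "two_variant",
               stringsAsFactors = FALSE)
  }))
  if (any(paste(truth$chrom, truth$pos) %in% variant_pos))
    stop("configured editing site coincides with a planted DNA variant")
  if (anyDuplicated(truth[, c("chrom", "pos", "sample")]))
    stop("two editing events configured at the same site and sample")
  # site inventory: every edited site plus background exonic sites
  site_tbl <- unique(truth[, c("chrom", "pos", "gene", "from_base")])
  if (n_background_sites > 0) {
    bg <- do.call(rbind, lapply(names(models), function(gid) {
      m <- models[[gid]]
      tx_len <- interval_bp(m$exons)
      picked <- 0; rows <- list()
      for (attempt in seq_len(50 * n_background_sites)) {
        if (picked >= n_background_sites) break
        t <- sample(tx_len, 1)
        gpos <- tx_to_genomic(m, t)
        key <- paste(m$chrom, gpos)
        if (key %in% variant_pos || key %in% paste(site_tbl$chrom, site_tbl$pos))
          next
        picked <- picked + 1
        rows[[picked]] <- data.frame(
          chrom = m$chrom, pos = gpos, gene = gid,
          from_base = as.character(
            Biostrings::subseq(genome[[m$chrom]], gpos, gpos)),
          stringsAsFactors = FALSE)
      }
      do.call(rbind, rows)
    }))
    site_tbl <- unique(rbind(site_tbl, bg))
  }
  zero_counts <- function() stats::setNames(as.list(rep(0L, 6)),
                                            c(dna_bases, "del", "ins"))
  pile_row <- function(chrom, pos, sample, counts)
    cbind(data.frame(chrom = chrom, pos = pos, sample = sample,
                     stringsAsFactors = FALSE),
          as.data.frame(counts))
  dna <- list(); rna <- list()
  for (i in seq_len(nrow(site_tbl))) {
    s <- site_tbl[i, ]
    for (ind in c("WF", "WM")) {
      depth <- stats::rpois(1, config$dna_depth_mean)
      counts <- zero_counts()
      counts[[s$from_base]] <- depth  # no DNA variant at these sites
      dna[[length(dna) + 1]] <- pile_row(s$chrom, s$pos, ind, counts)
    }
    for (smp in samples) {
      depth <- stats::rpois(1, config$rna_depth_mean)
      counts <- zero_counts()
      ev <- truth[truth$chrom == s$chrom & truth$pos == s$pos &
                    truth$sample == smp, , drop = FALSE]
      if (nrow(ev) == 1) {
        k <- stats::rbinom(1, depth, ev$fraction)
        counts[[ev$to_base]] <- k
        counts[[s$from_base]] <- depth - k
      } else {
        counts[[s$from_base]] <- depth
      }
      rna[[length(rna) + 1]] <- pile_row(s$chrom, s$pos, smp, counts)
    }
  }
  # expression: expressed genes comfortably above the floor everywhere,
  # unexpressed genes an order of magnitude below it in every sample
  gene_counts <- do.call(rbind, lapply(names(models), function(gid) {
    m <- models[[gid]]
    exon_len <- interval_bp(m$exons)
    rpkm_target <- if (gid %in% unexpressed)
      stats::runif(length(samples), 0.01, 0.2)
    else
      stats::runif(length(samples), 5 * config$rpkm_floor,
                   50 * config$rpkm_floor)
    reads <- pmax(round(rpkm_target * exon_len * config$library_size / 1e9),
                  if (gid %in% unexpressed) 0 else 1)
    data.frame(gene_id = gid, sample = samples, reads = reads,
               stringsAsFactors = FALSE)
  }))
  list(dna_pileups = do.call(rbind, dna),
       rna_pileups = do.call(rbind, rna),
       gene_counts = gene_counts,
       library_sizes = stats::setNames(rep(config$library_size,
                                           length(samples)), samples),
       truth = truth)
}

#' Write a genome and annotation to disk
#' @param genome_obj from [generate_genome()].
#' @param fasta_path,gff3_path output paths.
#' @return Invisibly, the two paths.
#' @export
write_genome <- function(genome_obj, fasta_path, gff3_path) {
  Biostrings::writeXStringSet(genome_obj$genome, fasta_path)
  write_gene_models_gff3(genome_obj$models, gff3_path)
  invisible(c(fasta_path, gff3_path))
}

#' Read a genome FASTA
#' @param path FASTA file.
#' @return Named `DNAStringSet`.
#' @export
read_genome <- function(path) {
  g <- Biostrings::readDNAStringSet(path)
  names(g) <- sub("\\s.*$", "", names(g))
  g
}

#' Write/read pileup and count tables
#'
#' Plain TSV with a header row; columns as produced by
#' [generate_rna_pileups()].
#' @param x table to write.
#' @param path file path.
#' @return `path` invisibly, or the table.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path)
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
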
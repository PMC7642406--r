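#' Variant record tables
#'
#' Variants are carried as a plain `data.frame` with one row per VCF record
#' (multi-allelic lines are kept intact, because the 1/2 genotype class —
#' heterozygous with two non-reference alleles — is a first-class category
#' in this analysis). Columns:
#' \describe{
#'   \item{chrom, pos}{chromosome and 1-based position}
#'   \item{ref, alt}{reference allele and comma-joined alternate alleles}
#'   \item{gt}{raw genotype string, e.g. "0/1"}
#'   \item{genotype_class}{one of `hom_ref`, `het_ref_alt`, `hom_alt`,
#'     `het_alt_alt`}
#'   \item{kind}{`snp` or `indel`}
#'   \item{QD, FS, MQRS, HS, RPRS, DP}{site quality metrics}
#'   \item{filter_status}{semicolon-joined failed-filter names, "" = PASS}
#'   \item{flag}{data-integrity flags raised while reading, "" = clean}
#' }
#' @name variant-tables
NULL

variant_metric_cols <- c("QD", "FS", "MQRS", "HS", "RPRS", "DP")

#' Derive the genotype class from a GT string
#'
#' `0/1` is heterozygous reference/alternate, `1/1` homozygous alternate
#' (only one allele seen, different from the reference), `1/2` heterozygous
#' with two distinct non-reference alleles, `0/0` homozygous reference.
#' Phased separators are accepted.
#'
#' @param gt character vector of GT strings.
#' @return character vector of genotype classes; `NA` for unparseable GT.
#' @export
genotype_class <- function(gt) {
  parts <- strsplit(gt, "[/|]")
  vapply(parts, function(p) {
    if (length(p) != 2 || anyNA(suppressWarnings(a <- as.integer(p))))
      return(NA_character_)
    a <- sort(a)
    if (a[1] == 0 && a[2] == 0) "hom_ref"
    else if (a[1] == 0) "het_ref_alt"
    else if (a[1] == a[2]) "hom_alt"
    else "het_alt_alt"
  }, character(1))
}

classify_kind <- function(ref, alt) {
  alts <- strsplit(alt, ",", fixed = TRUE)
  ifelse(nchar(ref) == 1 &
           vapply(alts, function(a) all(nchar(a) == 1), logical(1)),
         "snp", "indel")
}

#' Read variants from a VCF file
#'
#' One row per VCF line; multi-allelic records are preserved unsplit. The
#' genotype class is derived from the first sample's GT. Records with a
#' malformed GT or a genotype referring to a missing alternate allele are
#' flagged in the `flag` column rather than dropped.
#'
#' @param path VCF 4.x file (optionally gzipped).
#' @param info_keys named character vector mapping the canonical metric
#'   names `QD, FS, MQRS, HS, RPRS, DP` to the INFO keys used in the file.
#' @return A variant `data.frame` (see [variant-tables]).
#' @export
read_variants <- function(path,
                          info_keys = c(QD = "QD", FS = "FS", MQRS = "MQRS",
                                        HS = "HS", RPRS = "RPRS", DP = "DP")) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(fix) || nrow(v@fix) == 0) return(empty_variants())
  if (!is.matrix(fix))  # single-record files come back as a bare vector
    fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  out <- data.frame(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = fix$REF,
    alt = fix$ALT,
    stringsAsFactors = FALSE
  )
  gt <- tryCatch(vcfR::extract.gt(v, element = "GT")[, 1],
                 error = function(e) rep(NA_character_, nrow(out)))
  out$gt <- unname(gt)
  out$genotype_class <- genotype_class(out$gt)
  out$kind <- classify_kind(out$ref, out$alt)
  for (canon in variant_metric_cols) {
    key <- info_keys[[canon]]
    val <- suppressWarnings(
      as.numeric(vcfR::extract.info(v, element = key)))
    out[[canon]] <- if (length(val) == nrow(out)) val else NA_real_
  }
  out$filter_status <- ""
  out$flag <- ""
  bad_gt <- is.na(out$genotype_class)
  out$flag[bad_gt] <- "malformed_gt"
  n_alts <- lengths(strsplit(out$alt, ",", fixed = TRUE))
  max_idx <- vapply(strsplit(out$gt, "[/|]"), function(p) {
    a <- suppressWarnings(as.integer(p))
    if (anyNA(a)) NA_integer_ else max(a)
  }, integer(1))
  inconsistent <- !is.na(max_idx) & max_idx > n_alts
  out$flag[inconsistent] <- paste0(out$flag[inconsistent],
                                   ifelse(out$flag[inconsistent] == "", "", ";"),
                                   "gt_allele_missing")
  out
}

empty_variants <- function() {
  out <- data.frame(chrom = character(0), pos = integer(0),
                    ref = character(0), alt = character(0),
                    gt = character(0), genotype_class = character(0),
                    kind = character(0), stringsAsFactors = FALSE)
  for (m in variant_metric_cols) out[[m]] <- numeric(0)
  out$filter_status <- character(0)
  out$flag <- character(0)
  out
}

#' Write a variant table to VCF
#'
#' @param variants variant `data.frame`.
#' @param path output path; vcfR writes bgzip-compressed text, so a
#'   `.vcf.gz` suffix is conventional.
#' @param sample_id sample column name.
#' @return `path`, invisibly.
#' @export
write_variants_vcf <- function(variants, path, sample_id = "sample") {
  n <- nrow(variants)
  info <- if (n == 0) character(0) else {
    apply(as.matrix(variants[, variant_metric_cols]), 1, function(r) {
      paste0(variant_metric_cols, "=", ifelse(is.na(r), ".", r),
             collapse = ";")
    })
  }
  fix <- matrix(NA_character_, nrow = n, ncol = 8,
                dimnames = list(NULL, c("CHROM", "POS", "ID", "REF", "ALT",
                                        "QUAL", "FILTER", "INFO")))
  if (n > 0) {
    fix[, "CHROM"] <- variants$chrom
    fix[, "POS"] <- as.character(variants$pos)
    fix[, "ID"] <- "."
    fix[, "REF"] <- variants$ref
    fix[, "ALT"] <- variants$alt
    fix[, "QUAL"] <- "."
    fs <- variants$filter_status
    if (is.null(fs)) fs <- rep("", n)
    fix[, "FILTER"] <- ifelse(fs == "", "PASS", fs)
    fix[, "INFO"] <- info
  }
  gt <- matrix(c(rep("GT", n), variants$gt), nrow = n,
               dimnames = list(NULL, c("FORMAT", sample_id)))
  meta <- c(
    "##fileformat=VCFv4.2",
    paste0("##INFO=<ID=", variant_metric_cols,
           ",Number=1,Type=Float,Description=\"Site quality metric\">"),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">"
  )
  v <- methods::new(methods::getClass("vcfR", where = asNamespace("vcfR")),
                    meta = meta, fix = fix, gt = gt)
  vcfR::write.vcf(v, file = path)
  invisible(path)
}

#' Hard-filter thresholds
#'
#' The conservative post-calling hard filters applied to raw variant calls.
#' Each named filter fails a record when its metric crosses the bound:
#' \describe{
#'   \item{LowCovFilter}{depth `DP <= low_cov` (default 20)}
#'   \item{QDFilter}{quality by depth `QD < qd_min` (default 2.0)}
#'   \item{MQFilter}{mapping-quality rank-sum `MQRS < mq_rank_min`
#'     (default -12.5)}
#'   \item{FSFilter}{Fisher strand bias `FS > fs_max_snp` for SNPs
#'     (default 60) or `fs_max_indel` for indels (default 200)}
#'   \item{HaplotypeFilter}{haplotype score `HS > haplotype_max`
#'     (default 13)}
#'   \item{ReadPosFilter}{read-position rank-sum `RPRS < readpos_min_snp`
#'     (default -8) or `readpos_min_indel` (default -20) for indels}
#' }
#'
#' @param low_cov,qd_min,mq_rank_min,fs_max_snp,fs_max_indel,haplotype_max,readpos_min_snp,readpos_min_indel
#'   filter bounds; defaults as above.
#' @return A named list of thresholds.
#' @export
filter_thresholds <- function(low_cov = 20, qd_min = 2.0,
                              mq_rank_min = -12.5, fs_max_snp = 60.0,
                              fs_max_indel = 200.0, haplotype_max = 13.0,
                              readpos_min_snp = -8.0,
                              readpos_min_indel = -20.0) {
  t <- list(low_cov = low_cov, qd_min = qd_min, mq_rank_min = mq_rank_min,
            fs_max_snp = fs_max_snp, fs_max_indel = fs_max_indel,
            haplotype_max = haplotype_max,
            readpos_min_snp = readpos_min_snp,
            readpos_min_indel = readpos_min_indel)
  stopifnot(all(vapply(t, is.finite, logical(1))))
  t
}

#' Apply hard filters to a variant table
#'
#' Evaluates every named filter on every record and records all failures in
#' `filter_status` (semicolon-joined; "" means PASS). SNP- and indel-
#' specific bounds are selected by the record's `kind`. A filter whose
#' metric is missing is simply not evaluated unless `strict = TRUE`, in
#' which case missing metrics raise an error.
#'
#' @param variants variant `data.frame`.
#' @param thresholds from [filter_thresholds()].
#' @param strict error on missing metrics instead of skipping the filter.
#' @return The table with `filter_status` populated.
#' @export
apply_hard_filters <- function(variants, thresholds = filter_thresholds(),
                               strict = FALSE) {
  t <- thresholds
  is_indel <- variants$kind == "indel"
  checks <- list(
    LowCovFilter   = variants$DP <= t$low_cov,
    QDFilter       = variants$QD < t$qd_min,
    MQFilter       = variants$MQRS < t$mq_rank_min,
    FSFilter       = variants$FS > ifelse(is_indel, t$fs_max_indel,
                                          t$fs_max_snp),
    HaplotypeFilter = variants$HS > t$haplotype_max,
    ReadPosFilter  = variants$RPRS < ifelse(is_indel, t$readpos_min_indel,
                                            t$readpos_min_snp)
  )
  if (strict && any(vapply(checks, anyNA, logical(1))))
    stop("missing quality metric in strict filtering mode")
  fails <- vapply(names(checks), function(nm) {
    f <- checks[[nm]]
    ifelse(!is.na(f) & f, nm, "")
  }, character(nrow(variants)))
  if (nrow(variants) == 1) fails <- matrix(fails, nrow = 1,
                                           dimnames = list(NULL, names(checks)))
  variants$filter_status <- apply(fails, 1, function(r)
    paste(r[r != ""], collapse = ";"))
  variants
}

#' Keep only records passing all hard filters
#' @param variants a table processed by [apply_hard_filters()].
#' @return The passing subset.
#' @export
passing_variants <- function(variants) {
  variants[variants$filter_status == "", , drop = FALSE]
}

#' Is a substitution a transition?
#'
#' Transitions are the purine-purine and pyrimidine-pyrimidine exchanges
#' (A<->G, C<->T); the other four unordered base pairings are transversions.
#'
#' @param ref,alt single bases in `A,C,G,T`; vectors recycle.
#' @return Logical vector.
#' @examples
#' is_transition("A", "G")  # TRUE
#' is_transition("A", "C")  # FALSE
#' @export
is_transition <- function(ref, alt) {
  bases <- c("A", "C", "G", "T")
  if (!all(ref %in% bases) || !all(alt %in% bases))
    stop("alleles must be single bases A, C, G or T")
  if (any(ref == alt)) stop("ref and alt must differ")
  purine <- c(A = TRUE, C = FALSE, G = TRUE, T = FALSE)
  purine[ref] == purine[alt]
}
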
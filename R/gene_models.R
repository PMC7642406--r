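#' Construct a gene model
#'
#' A stranded protein-coding gene with one transcript: exon intervals and
#' their CDS / UTR partition. All coordinates are 1-based inclusive genomic
#' positions; interval tables have `start`/`end` columns sorted by genomic
#' position. Transcription order is derived from `strand` where needed.
#'
#' @param gene_id identifier.
#' @param chrom chromosome name.
#' @param strand "+" or "-".
#' @param start,end gene span.
#' @param exons,cds,utr5,utr3 interval `data.frame`s (start, end); UTRs
#'   may be empty.
#' @return A `gene_model` object (list).
#' @export
gene_model <- function(gene_id, chrom, strand, start, end,
                       exons, cds, utr5 = empty_intervals(),
                       utr3 = empty_intervals()) {
  stopifnot(strand %in% c("+", "-"), start >= 1, end >= start)
  exons <- sort_intervals(exons); cds <- sort_intervals(cds)
  utr5 <- sort_intervals(utr5); utr3 <- sort_intervals(utr3)
  cds_len <- interval_bp(cds)
  if (cds_len %% 3 != 0)
    stop("total CDS length must be a multiple of 3 for gene ", gene_id)
  for (iv in list(exons, cds, utr5, utr3)) {
    if (nrow(iv) && (min(iv$start) < start || max(iv$end) > end))
      stop("feature interval outside gene span for gene ", gene_id)
  }
  structure(list(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = end, exons = exons, cds = cds,
                 utr5 = utr5, utr3 = utr3, cds_len = cds_len),
            class = "gene_model")
}

empty_intervals <- function()
  data.frame(start = integer(0), end = integer(0))

sort_intervals <- function(iv) {
  iv <- as.data.frame(iv)[, c("start", "end")]
  iv <- iv[order(iv$start), , drop = FALSE]
  if (nrow(iv) > 1 && any(iv$start[-1] <= iv$end[-nrow(iv)]))
    stop("intervals overlap")
  rownames(iv) <- NULL
  iv
}

interval_bp <- function(iv) if (nrow(iv) == 0) 0 else
  sum(as.numeric(iv$end) - as.numeric(iv$start) + 1)

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s %s:%d-%d (%s), %d exon(s), CDS %d bp\n",
              x$gene_id, x$chrom, x$start, x$end, x$strand,
              nrow(x$exons), x$cds_len))
  invisible(x)
}

#' Read gene models from a GFF3 file
#'
#' Expects gene / mRNA / exon / CDS / five_prime_UTR / three_prime_UTR
#' features with one transcript per gene.
#'
#' @param path GFF3 file.
#' @return Named list of [gene_model()] objects.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  df <- as.data.frame(gr)
  genes <- df[df$type == "gene", , drop = FALSE]
  models <- lapply(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    gid <- g$ID
    mrna <- df[df$type == "mRNA" &
                 vapply(df$Parent, function(p) gid %in% p, logical(1)), ]
    tid <- if (nrow(mrna)) mrna$ID[1] else gid
    kids <- df[vapply(df$Parent, function(p) tid %in% p, logical(1)), ]
    pick <- function(type) {
      k <- kids[kids$type == type, c("start", "end")]
      if (nrow(k) == 0) empty_intervals() else k
    }
    gene_model(gene_id = gid, chrom = as.character(g$seqnames),
               strand = as.character(g$strand), start = g$start, end = g$end,
               exons = pick("exon"), cds = pick("CDS"),
               utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
  })
  names(models) <- vapply(models, `[[`, character(1), "gene_id")
  models
}

#' Write gene models to GFF3
#'
#' @param models list of [gene_model()] objects.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_models_gff3 <- function(models, path) {
  lines <- c("##gff-version 3")
  for (m in models) {
    attr_gene <- sprintf("ID=%s", m$gene_id)
    tid <- paste0(m$gene_id, ".t1")
    fmt <- function(type, s, e, attrs)
      sprintf("%s\tvariscape\t%s\t%d\t%d\t.\t%s\t%s\t%s",
              m$chrom, type, s, e, m$strand,
              if (type == "CDS") "0" else ".", attrs)
    lines <- c(lines,
               fmt("gene", m$start, m$end, attr_gene),
               fmt("mRNA", m$start, m$end,
                   sprintf("ID=%s;Parent=%s", tid, m$gene_id)))
    emit <- function(iv, type) {
      if (nrow(iv) == 0) return(character(0))
      vapply(seq_len(nrow(iv)), function(i)
        fmt(type, iv$start[i], iv$end[i], sprintf("Parent=%s", tid)),
        character(1))
    }
    lines <- c(lines, emit(m$exons, "exon"), emit(m$cds, "CDS"),
               emit(m$utr5, "five_prime_UTR"), emit(m$utr3, "three_prime_UTR"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Offset of a genomic position within the coding sequence
#'
#' 0-based offset in transcription order (position 0 is the A of the start
#' codon). `NA` for positions outside the CDS.
#'
#' @param model a [gene_model()].
#' @param pos genomic position (1-based), vectorized.
#' @return integer offsets.
#' @export
cds_offset <- function(model, pos) {
  cds <- model$cds
  vapply(pos, function(p) {
    hit <- which(cds$start <= p & cds$end >= p)
    if (length(hit) == 0) return(NA_integer_)
    if (model$strand == "+") {
      before <- if (hit > 1) sum(cds$end[seq_len(hit - 1)] -
                                   cds$start[seq_len(hit - 1)] + 1L) else 0L
      as.integer(before + (p - cds$start[hit]))
    } else {
      n <- nrow(cds)
      after <- if (hit < n) sum(cds$end[(hit + 1):n] -
                                  cds$start[(hit + 1):n] + 1L) else 0L
      as.integer(after + (cds$end[hit] - p))
    }
  }, integer(1))
}

#' Spliced coding sequence of a gene
#'
#' @param model a [gene_model()].
#' @param genome named `DNAStringSet`.
#' @return `DNAString` of the CDS on the coding strand.
#' @export
coding_sequence <- function(model, genome) {
  chrom_seq <- genome[[model$chrom]]
  pieces <- lapply(seq_len(nrow(model$cds)), function(i)
    Biostrings::subseq(chrom_seq, model$cds$start[i], model$cds$end[i]))
  s <- do.call(Biostrings::xscat, pieces)
  if (model$strand == "-") s <- Biostrings::reverseComplement(s)
  s
}
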
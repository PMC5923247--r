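#' Export an isoform catalog as GTF
#'
#' Writes one transcript per isoform, with exon features taken from the
#' gene model's included exons. Transcript ids are
#' `<gene_id>.iso<code>` using the integer composition code. Internal
#' half-open coordinates are converted to the GTF 1-based closed
#' convention.
#'
#' @param isoforms K x E binary matrix (or list) of compositions.
#' @param gene A [gene_model()].
#' @param file Output path.
#' @export
write_isoform_gtf <- function(isoforms, gene, file) {
  isoforms <- as_catalog(isoforms, gene$E)
  feats <- list()
  for (k in seq_len(nrow(isoforms))) {
    code <- encode_isoform(isoforms[k, ])
    tx <- sprintf("%s.iso%.0f", gene$gene_id, code)
    keep <- which(isoforms[k, ] == 1L)
    ex <- gene$exons[keep, , drop = FALSE]
    feats[[length(feats) + 1L]] <- data.frame(
      type = c("transcript", rep("exon", nrow(ex))),
      start = c(min(ex$start), ex$start),
      end = c(max(ex$end), ex$end) - 1L,
      transcript_id = tx)
  }
  df <- do.call(rbind, feats)
  gr <- GenomicRanges::GRanges(
    seqnames = gene$chrom,
    ranges = IRanges::IRanges(df$start, df$end),
    strand = gene$strand,
    type = df$type, gene_id = gene$gene_id,
    transcript_id = df$transcript_id,
    source = "spliceHDP")
  rtracklayer::export(gr, file, format = "gtf")
  invisible(file)
}

#' Import isoform compositions from a GTF
#'
#' Reads transcripts from a GTF and converts each to a binary
#' composition against `gene`'s exon set. Exon identification is
#' lenient: a transcript exon partially overlapping a reference exon
#' snaps to that exon's index (so partially reconstructed exons count
#' as present).
#'
#' @param file GTF path.
#' @param gene A [gene_model()].
#' @return K x E binary matrix with transcript ids as rownames.
#' @export
compositions_from_gtf <- function(file, gene) {
  gr <- rtracklayer::import(file)
  gr <- gr[gr$type == "exon"]
  tx <- as.character(gr$transcript_id)
  ref <- IRanges::IRanges(gene$exons$start, gene$exons$end - 1L)
  comp <- lapply(split(seq_along(gr), tx), function(idx) {
    q <- IRanges::IRanges(GenomicRanges::start(gr)[idx],
                          GenomicRanges::end(gr)[idx])
    hits <- IRanges::findOverlaps(q, ref)
    v <- rep(0L, gene$E)
    v[unique(S4Vectors::subjectHits(hits))] <- 1L
    v
  })
  out <- do.call(rbind, comp)
  rownames(out) <- names(comp)
  out
}

#' Write / read per-sample isoform proportions as TSV
#'
#' @param psi m x K matrix (samples x transcripts) with transcript codes
#'   as column names.
#' @param file Path.
#' @export
write_proportions <- function(psi, file) {
  df <- data.frame(sample_id = rownames(psi) %||% seq_len(nrow(psi)),
                   psi, check.names = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_proportions
#' @export
read_proportions <- function(file) {
  df <- utils::read.delim(file, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a flat key=value configuration file
#'
#' Lines of the form `key = value`; values that parse as numbers become
#' numeric. Blank lines and `#` comments are ignored. Useful for
#' supplying [hyperparameters()] and [fit_config()] fields from the
#' command line.
#'
#' @param file Path.
#' @return Named list.
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed config line: ", ln)
    key <- trimws(kv[1L])
    val <- trimws(kv[2L])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (is.na(num)) val else num
  }
  out
}

#' Write simulated reads as a minimal SAM file
#'
#' Emits mandatory-column SAM records for read tables carrying `start`,
#' `end` and `exons` (as from [simulate_gene_reads()] or
#' [fragment_long_reads()]): CIGAR strings contain `M` segments split by
#' `N` intron skips derived from the gene model.
#'
#' @param reads data.frame with `start`, `end`, `exons` columns.
#' @param gene A [gene_model()].
#' @param file Output path.
#' @export
write_sam <- function(reads, gene, file) {
  con <- file(file, "w")
  on.exit(close(con))
  seqlen <- max(gene$exons$end) + 1000L
  writeLines(c("@HD\tVN:1.6\tSO:coordinate",
               sprintf("@SQ\tSN:%s\tLN:%d", gene$chrom, seqlen)), con)
  ex <- gene$exons[order(gene$exons$start), , drop = FALSE]
  o <- order(reads$start)
  for (i in o) {
    exset <- sort(match(parse_exons(reads$exons[i])[[1L]],
                        order(gene$exons$start)))
    segs <- character(0)
    pos <- reads$start[i]
    for (jj in seq_along(exset)) {
      e <- exset[jj]
      s0 <- max(pos, ex$start[e])
      s1 <- min(reads$end[i], ex$end[e])
      segs <- c(segs, sprintf("%dM", s1 - s0))
      if (jj < length(exset))
        segs <- c(segs, sprintf("%dN", ex$start[exset[jj + 1L]] - ex$end[e]))
    }
    qn <- if ("qname" %in% colnames(reads)) reads$qname[i] else
      sprintf("read%06d", i)
    writeLines(sprintf("%s\t0\t%s\t%d\t60\t%s\t*\t0\t0\t*\t*",
                       qn, gene$chrom, reads$start[i],
                       paste(segs, collapse = "")), con)
  }
  invisible(file)
}
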
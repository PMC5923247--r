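#' Construct a gene model from exon intervals
#'
#' A gene model is an ordered list of non-overlapping exon intervals in
#' half-open genomic coordinates `[start, end)`, ordered 5' to 3' along the
#' direction of transcription (exon 1 is the 5'-most exon; on the minus
#' strand that is the interval with the largest coordinates). Retained
#' introns may be modelled as additional "exons".
#'
#' @param gene_id Character scalar identifying the gene.
#' @param exon_starts,exon_ends Integer vectors of equal length giving
#'   half-open exon intervals in genomic coordinates. Overlapping or
#'   book-ended intervals are collapsed.
#' @param strand `"+"` or `"-"`.
#' @param chrom Chromosome / sequence name (used when exporting GTF).
#' @return An object of class `gene_model` with fields `gene_id`, `exons`
#'   (data.frame of `start`, `end` in transcription order), `E` (exon
#'   count), `strand` and `chrom`.
#' @export
gene_model <- function(gene_id, exon_starts, exon_ends, strand = "+",
                       chrom = "chr1") {
  if (length(exon_starts) != length(exon_ends) || length(exon_starts) < 1L)
    stop("need >= 1 exon interval with matching starts and ends")
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  if (any(exon_ends <= exon_starts))
    stop("exon ends must exceed starts (half-open intervals)")
  ir <- IRanges::reduce(IRanges::IRanges(start = as.integer(exon_starts),
                                         end = as.integer(exon_ends) - 1L))
  ex <- data.frame(start = IRanges::start(ir), end = IRanges::end(ir) + 1L)
  ex <- ex[order(ex$start), , drop = FALSE]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  rownames(ex) <- NULL
  structure(list(gene_id = as.character(gene_id), exons = ex,
                 E = nrow(ex), strand = strand,
                 chrom = as.character(chrom)),
            class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("gene_model %s (%s strand): %d exon%s, %d exonic bp\n",
              x$gene_id, x$strand, x$E, if (x$E == 1L) "" else "s",
              transcript_span(x)))
  invisible(x)
}

#' Total exonic length of a gene model (bp)
#' @param gene A [gene_model()].
#' @export
transcript_span <- function(gene) {
  sum(gene$exons$end - gene$exons$start)
}

exon_lengths <- function(gene) gene$exons$end - gene$exons$start

#' Import gene annotation records
#'
#' Thin wrapper over [rtracklayer::import()] returning annotation records
#' (GFF3/GTF, GENCODE dialect accepted) suitable for [build_gene_model()].
#'
#' @param path Path to a GFF3 or GTF file.
#' @return A `GRanges` of annotation records.
#' @export
read_gene_annotation <- function(path) {
  rtracklayer::import(path)
}

#' Build the representative gene model for one gene
#'
#' Selects a single representative transcript for `gene_id` and returns its
#' exons as a [gene_model()]. When transcripts are flagged as representative
#' (a `tag` field containing `"basic"`), only those are considered; among
#' candidates, the transcript with the largest number of exons wins (ties
#' broken by transcript id). Exons of the chosen transcript are collapsed
#' into a standard non-overlapping set. Annotation coordinates are 1-based
#' closed and are converted to the package's half-open convention.
#'
#' @param records A `GRanges` from [read_gene_annotation()] or a data.frame
#'   with columns `type`, `start`, `end`, `strand`, `gene_id`,
#'   `transcript_id` (and optionally `tag`).
#' @param gene_id Gene identifier to extract.
#' @return A [gene_model()].
#' @export
build_gene_model <- function(records, gene_id) {
  if (methods::is(records, "GRanges")) {
    df <- data.frame(chrom = as.character(GenomicRanges::seqnames(records)),
                     start = GenomicRanges::start(records),
                     end = GenomicRanges::end(records),
                     strand = as.character(GenomicRanges::strand(records)),
                     stringsAsFactors = FALSE)
    mc <- S4Vectors::mcols(records)
    for (col in c("type", "gene_id", "transcript_id", "tag")) {
      if (col %in% colnames(mc)) {
        v <- mc[[col]]
        df[[col]] <- vapply(as.list(v), function(e)
          paste(as.character(e), collapse = ","), character(1))
      }
    }
    records <- df
  }
  need <- c("type", "start", "end", "gene_id", "transcript_id")
  if (!all(need %in% colnames(records)))
    stop("annotation records lack required fields: ",
         paste(setdiff(need, colnames(records)), collapse = ", "))
  gr <- records[records$gene_id == gene_id, , drop = FALSE]
  if (nrow(gr) == 0L) stop("gene not found in annotation: ", gene_id)
  tx_ids <- unique(gr$transcript_id[gr$type %in% c("transcript", "mRNA", "exon")])
  tx_ids <- tx_ids[!is.na(tx_ids) & nzchar(tx_ids)]
  if (length(tx_ids) == 0L) stop("no transcripts annotated for gene ", gene_id)
  if ("tag" %in% colnames(gr)) {
    flagged <- unique(gr$transcript_id[grepl("basic", gr$tag) &
                                         !is.na(gr$transcript_id)])
    if (length(flagged) > 0L) tx_ids <- intersect(tx_ids, flagged)
  }
  n_ex <- vapply(tx_ids, function(tx)
    sum(gr$type == "exon" & gr$transcript_id == tx), integer(1))
  if (any(n_ex == 0L))
    stop("malformed annotation: transcript without exons for gene ", gene_id)
  tx_ids <- tx_ids[order(-n_ex, tx_ids)]
  chosen <- gr[gr$type == "exon" & gr$transcript_id == tx_ids[1L], , drop = FALSE]
  strand <- if ("strand" %in% colnames(chosen) &&
                any(chosen$strand == "-")) "-" else "+"
  chrom <- if ("chrom" %in% colnames(chosen)) chosen$chrom[1L] else "chr1"
  # 1-based closed annotation -> half-open
  gene_model(gene_id, chosen$start, chosen$end + 1L, strand = strand,
             chrom = chrom)
}

## -- transcript-coordinate helpers -----------------------------------------
## Transcript coordinates are 0-based offsets along the concatenated exons
## in transcription order.

tx_breaks <- function(gene) {
  c(0L, cumsum(exon_lengths(gene)))
}

## genomic position (of a base) -> transcript offset; NA if intronic
genomic_to_tx <- function(gene, gpos) {
  ex <- gene$exons
  br <- tx_breaks(gene)
  out <- rep(NA_integer_, length(gpos))
  for (i in seq_len(gene$E)) {
    inside <- gpos >= ex$start[i] & gpos < ex$end[i]
    if (!any(inside)) next
    off <- if (gene$strand == "+") gpos[inside] - ex$start[i] else
      ex$end[i] - 1L - gpos[inside]
    out[inside] <- br[i] + off
  }
  out
}

## transcript offset (of a base) -> genomic position
tx_to_genomic <- function(gene, tpos) {
  ex <- gene$exons
  br <- tx_breaks(gene)
  i <- findInterval(tpos, br, rightmost.closed = FALSE)
  bad <- tpos < 0L | tpos >= br[gene$E + 1L]
  if (any(bad)) stop("transcript offset outside gene")
  off <- tpos - br[i]
  if (gene$strand == "+") ex$start[i] + off else ex$end[i] - 1L - off
}

## exon index containing each transcript offset
tx_to_exon <- function(gene, tpos) {
  findInterval(tpos, tx_breaks(gene), rightmost.closed = FALSE)
}
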
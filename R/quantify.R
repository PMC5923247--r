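#' Allocate a gene's mapped reads to transcripts
#'
#' The number of reads assigned to transcript t in a sample is the
#' product of the total number of reads mapped to the gene in that
#' sample and the sample's isoform proportion: `X_t = total * psi_t`.
#' Conservation is exact.
#'
#' @param gene_read_total Nonnegative scalar: reads mapped to the gene.
#' @param psi_row Simplex of per-transcript proportions.
#' @return Numeric vector of allocated read counts (real-valued).
#' @export
allocate_reads <- function(gene_read_total, psi_row) {
  if (gene_read_total < 0) stop("gene_read_total must be >= 0")
  if (abs(sum(psi_row) - 1) > 1e-6 || any(psi_row < 0))
    stop("psi_row must be a simplex")
  gene_read_total * psi_row
}

#' Reads per kilobase of exon per million mapped reads
#'
#' `RPKM_t = 1e9 * X_t / (L_t * N)` where `X_t` is the number of reads
#' allocated to transcript t, `L_t` its exonic length in bp, and `N` the
#' sample's total mapped reads.
#'
#' @param x_t Allocated reads (nonnegative; vectorised).
#' @param l_t Transcript length in bp (> 0).
#' @param n Total mapped reads in the sample (> 0).
#' @return RPKM values.
#' @export
rpkm <- function(x_t, l_t, n) {
  if (any(l_t <= 0)) stop("transcript length must be positive")
  if (any(n <= 0)) stop("library size must be positive")
  1e9 * x_t / (l_t * n)
}

#' Transcript ratios within a gene-sample
#'
#' `ratio_t = X_t / sum(X_t)`; when the gene has no allocated reads the
#' ratios are undefined and returned as `NA` (flagged missing).
#'
#' @param x_t Nonnegative allocated read counts for one gene-sample.
#' @return Ratio vector summing to 1, or all-`NA` for an unexpressed gene.
#' @export
transcript_ratios <- function(x_t) {
  if (any(x_t < 0)) stop("allocated counts must be >= 0")
  s <- sum(x_t)
  if (s == 0) return(rep(NA_real_, length(x_t)))
  x_t / s
}

#' Quantify a fitted model per sample and transcript
#'
#' Converts a fitted state into per-sample transcript read counts, RPKM
#' and transcript ratios. Reads mapped to the gene per sample are the
#' column sums of the read-term matrix; `library_sizes` defaults to
#' those totals (appropriate for single-gene runs; supply genome-wide
#' mapped-read totals when available).
#'
#' @param fit An `svi_fit`.
#' @param rtm The `read_term_matrix` the model was fitted to.
#' @param library_sizes Optional per-sample total mapped reads `N`.
#' @return data.frame with columns `gene_id`, `transcript_code`,
#'   `sample_id`, `reads`, `length`, `rpkm`, `ratio`.
#' @export
quantify <- function(fit, rtm, library_sizes = NULL) {
  gene <- fit$gene
  totals <- colSums(rtm$X)
  if (is.null(library_sizes)) library_sizes <- totals
  library_sizes <- rep_len(library_sizes, length(totals))
  K <- nrow(fit$isoforms)
  lens <- vapply(seq_len(K), function(k)
    isoform_length(gene, fit$isoforms[k, ]), numeric(1))
  out <- vector("list", length(totals))
  for (j in seq_along(totals)) {
    x_t <- allocate_reads(totals[j], fit$psi[j, ])
    out[[j]] <- data.frame(
      gene_id = gene$gene_id,
      transcript_code = fit$codes,
      sample_id = rtm$sample_ids[j],
      reads = as.numeric(x_t),
      length = lens,
      rpkm = if (library_sizes[j] > 0) rpkm(x_t, lens, library_sizes[j])
             else rep(0, K),
      ratio = transcript_ratios(as.numeric(x_t)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
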
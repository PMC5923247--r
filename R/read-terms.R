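#' Convert a mapped read into a read term
#'
#' A read term is the tuple (start, end, covered-exon set) summarising a
#' mapped read: the terminal base-pair positions of the read (half-open,
#' reported as leftmost genomic base and rightmost-exclusive) together with
#' the ordered set of exon indices it covers. The read is walked base by
#' base along the gene's exonic sequence from its 5' starting base for
#' `read_length` exonic bases, skipping introns. For a gene with first
#' exons `[1,67)` and `[2617,2865)`, a 100 bp read starting at coordinate
#' 40 covers 27 bases of exon 1 and 73 bases of exon 2, giving the term
#' `(40, 2690, {1,2})`.
#'
#' @param read_start Genomic coordinate of the read's 5'-most base; must
#'   fall inside an exon.
#' @param read_length Number of exonic bases covered by the read.
#' @param gene A [gene_model()].
#' @return A list with fields `start`, `end` (half-open genomic span) and
#'   `exons` (increasing exon indices in transcription order).
#' @export
read_to_term <- function(read_start, read_length, gene) {
  if (read_length < 1L) stop("read_length must be >= 1")
  t0 <- genomic_to_tx(gene, read_start)
  if (is.na(t0))
    stop("unmappable read: start position ", read_start,
         " is not inside an exon of ", gene$gene_id)
  t1 <- t0 + as.integer(read_length)
  if (t1 > transcript_span(gene))
    stop("read truncation: read overruns the last exon of ", gene$gene_id)
  e0 <- tx_to_exon(gene, t0)
  e1 <- tx_to_exon(gene, t1 - 1L)
  g_last <- tx_to_genomic(gene, t1 - 1L)
  if (gene$strand == "+") {
    list(start = as.integer(read_start), end = as.integer(g_last + 1L),
         exons = e0:e1)
  } else {
    list(start = as.integer(g_last), end = as.integer(read_start + 1L),
         exons = e0:e1)
  }
}

term_key <- function(start, end, exons_chr) {
  paste(start, end, exons_chr, sep = ":")
}

parse_exons <- function(s) lapply(strsplit(as.character(s), ","), as.integer)

#' Extract read terms from aligned reads
#'
#' Reads a coordinate-sorted SAM/BAM file, excludes unmapped, secondary,
#' duplicate and QC-fail alignments, reduces each remaining alignment to
#' its aligned reference span (soft clips and insertions ignored; `N`
#' skips treated as introns), and converts it to a read term against
#' `gene`. Reads starting in an intron or overrunning the gene's exons are
#' dropped and counted.
#'
#' @param file Path to a SAM or BAM file.
#' @param gene A [gene_model()].
#' @param min_mapq Minimum mapping quality (default 0).
#' @return A data.frame with columns `start`, `end`, `exons`
#'   (comma-joined) and `count`, with attributes `gene_id`, `n_used`,
#'   `n_dropped`.
#' @export
terms_from_alignments <- function(file, gene, min_mapq = 0L) {
  if (grepl("\\.sam$", file, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    file <- Rsamtools::asBam(file, destination = dest,
                             overwrite = TRUE, indexDestination = FALSE)
  }
  flags <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                  isSecondaryAlignment = FALSE,
                                  isDuplicate = FALSE,
                                  isNotPassingQualityControls = FALSE)
  par <- Rsamtools::ScanBamParam(flag = flags,
                                 what = c("pos", "cigar", "mapq"))
  aln <- Rsamtools::scanBam(file, param = par)[[1L]]
  keep <- !is.na(aln$pos) & (is.na(aln$mapq) | aln$mapq >= min_mapq)
  pos <- aln$pos[keep]
  cig <- aln$cigar[keep]
  ops <- cigar_lengths(cig)
  out <- vector("list", length(pos))
  dropped <- 0L
  for (i in seq_along(pos)) {
    exonic <- ops$exonic[i]
    start5 <- if (gene$strand == "+") pos[i] else pos[i] + ops$ref_span[i] - 1L
    term <- tryCatch(read_to_term(start5, exonic, gene), error = function(e) NULL)
    if (is.null(term)) { dropped <- dropped + 1L; next }
    out[[i]] <- data.frame(start = term$start, end = term$end,
                           exons = paste(term$exons, collapse = ","))
  }
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(start = integer(), end = integer(),
                      exons = character(), count = integer())
  } else {
    agg <- stats::aggregate(list(count = rep(1L, nrow(out))),
                            by = out[c("start", "end", "exons")], FUN = sum)
    out <- agg[order(agg$start, agg$end, agg$exons), , drop = FALSE]
    rownames(out) <- NULL
  }
  attr(out, "gene_id") <- gene$gene_id
  attr(out, "n_used") <- sum(out$count)
  attr(out, "n_dropped") <- dropped
  out
}

## per-alignment reference-consuming lengths from CIGAR strings:
## exonic = M/=/X/D (bases walked along exons), ref_span adds N skips
cigar_lengths <- function(cigars) {
  exonic <- integer(length(cigars))
  ref_span <- integer(length(cigars))
  m <- gregexpr("(\\d+)([MIDNSHP=X])", cigars)
  toks <- regmatches(cigars, m)
  for (i in seq_along(toks)) {
    n <- as.integer(sub("[A-Z=]$", "", toks[[i]]))
    op <- sub("^\\d+", "", toks[[i]])
    exonic[i] <- sum(n[op %in% c("M", "=", "X", "D")])
    ref_span[i] <- exonic[i] + sum(n[op == "N"])
  }
  list(exonic = exonic, ref_span = ref_span)
}

#' Build the read-term count matrix across samples
#'
#' Takes one term table per sample (as from [terms_from_alignments()], or
#' any data.frame with `start`, `end`, `exons` and optionally `count`),
#' forms the union catalog of read terms, and fills the V x m count
#' matrix; samples missing a term get 0.
#'
#' @param per_sample_terms Named list of per-sample term tables, all
#'   derived from the same gene.
#' @return An object of class `read_term_matrix`: list with `X` (V x m
#'   integer matrix), `catalog` (data.frame `start`, `end`, `exons`),
#'   `sample_ids`, and `gene_id` (may be `NA`).
#' @export
build_count_matrix <- function(per_sample_terms) {
  m <- length(per_sample_terms)
  if (m == 0L) stop("need at least one sample")
  ids <- names(per_sample_terms)
  if (is.null(ids)) ids <- paste0("sample", seq_len(m))
  genes <- unique(unlist(lapply(per_sample_terms, attr, "gene_id")))
  if (length(genes) > 1L)
    stop("mixed-gene input: samples reference genes ",
         paste(genes, collapse = ", "))
  tabs <- lapply(per_sample_terms, function(tt) {
    tt <- as.data.frame(tt)
    if (!"count" %in% colnames(tt)) tt$count <- 1L
    tt
  })
  keys <- lapply(tabs, function(tt) term_key(tt$start, tt$end, tt$exons))
  all_tab <- do.call(rbind, lapply(tabs, function(tt)
    tt[c("start", "end", "exons")]))
  all_keys <- unlist(keys)
  cat_idx <- !duplicated(all_keys)
  catalog <- all_tab[cat_idx, , drop = FALSE]
  o <- order(catalog$start, catalog$end, catalog$exons)
  catalog <- catalog[o, , drop = FALSE]
  rownames(catalog) <- NULL
  ckeys <- term_key(catalog$start, catalog$end, catalog$exons)
  X <- matrix(0L, nrow(catalog), m, dimnames = list(NULL, ids))
  for (j in seq_len(m)) {
    idx <- match(keys[[j]], ckeys)
    agg <- tapply(tabs[[j]]$count, idx, sum)
    X[as.integer(names(agg)), j] <- as.integer(agg)
  }
  new_read_term_matrix(X, catalog, ids,
                       if (length(genes)) genes else NA_character_)
}

new_read_term_matrix <- function(X, catalog, sample_ids, gene_id = NA) {
  structure(list(X = X, catalog = catalog, sample_ids = sample_ids,
                 gene_id = gene_id),
            class = "read_term_matrix")
}

#' @export
print.read_term_matrix <- function(x, ...) {
  cat(sprintf("read_term_matrix: %d read terms x %d samples, %d reads%s\n",
              nrow(x$X), ncol(x$X), sum(x$X),
              if (is.na(x$gene_id)) "" else paste0(" (", x$gene_id, ")")))
  invisible(x)
}

#' Collapse similar read terms toward a target catalog size
#'
#' Terms sharing an exon set whose start positions fall in the same
#' fixed-width bin are collapsed: counts are summed and the representative
#' term is the count-weighted modal term of the bin. The bin width is
#' chosen by bisection so the collapsed catalog size lands nearest
#' `target` (terms with distinct exon sets are never merged, so the result
#' cannot go below the number of distinct exon sets). The grand total of
#' counts is conserved exactly.
#'
#' @param rtm A `read_term_matrix`.
#' @param target Desired number of read terms (>= 1).
#' @return A collapsed `read_term_matrix`.
#' @export
reduce_catalog <- function(rtm, target) {
  stopifnot(inherits(rtm, "read_term_matrix"), target >= 1)
  V <- nrow(rtm$X)
  if (V <= target) return(rtm)
  grp <- rtm$catalog$exons
  starts <- rtm$catalog$start
  groups <- split(seq_len(V), grp)
  n_bins <- function(w) {
    sum(vapply(groups, function(idx) {
      s <- starts[idx]
      length(unique((s - min(s)) %/% w))
    }, numeric(1)))
  }
  lo <- 1L
  hi <- max(1L, max(starts) - min(starts) + 1L)
  while (lo < hi) {            # V(w) is (weakly) decreasing in w
    mid <- (lo + hi) %/% 2L
    if (n_bins(mid) > target) lo <- mid + 1L else hi <- mid
  }
  cand <- unique(pmax(1L, c(lo - 1L, lo)))
  w <- cand[which.min(abs(vapply(cand, n_bins, numeric(1)) - target))]
  tot <- rowSums(rtm$X)
  pieces <- lapply(groups, function(idx) {
    s <- starts[idx]
    bin <- (s - min(s)) %/% w
    lapply(split(idx, bin), function(rows) {
      cnt <- tot[rows]
      rep_row <- rows[order(-cnt, starts[rows])][1L]  # count-weighted mode
      list(rep_row = rep_row, rows = rows)
    })
  })
  pieces <- unlist(pieces, recursive = FALSE)
  rep_rows <- vapply(pieces, `[[`, numeric(1), "rep_row")
  o <- order(rtm$catalog$start[rep_rows], rtm$catalog$end[rep_rows])
  pieces <- pieces[o]
  rep_rows <- rep_rows[o]
  Xnew <- t(vapply(pieces, function(p)
    colSums(rtm$X[p$rows, , drop = FALSE]), numeric(ncol(rtm$X))))
  if (ncol(rtm$X) == 1L) Xnew <- matrix(Xnew, ncol = 1L)
  storage.mode(Xnew) <- "integer"
  colnames(Xnew) <- colnames(rtm$X)
  catalog <- rtm$catalog[rep_rows, , drop = FALSE]
  rownames(catalog) <- NULL
  new_read_term_matrix(Xnew, catalog, rtm$sample_ids, rtm$gene_id)
}

#' Write / read a read-term matrix as TSV
#'
#' Serialises the catalog and counts as a TSV with columns `term_index`,
#' `start`, `end`, `exons`, then one count column per sample.
#'
#' @param rtm A `read_term_matrix`.
#' @param file Path to write to / read from.
#' @param gene_id Optional gene id recorded when reading.
#' @export
write_term_matrix <- function(rtm, file) {
  df <- cbind(data.frame(term_index = seq_len(nrow(rtm$catalog))),
              rtm$catalog, as.data.frame(rtm$X))
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' @rdname write_term_matrix
#' @export
read_term_matrix_tsv <- function(file, gene_id = NA) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE,
                          check.names = FALSE)
  fixed <- c("term_index", "start", "end", "exons")
  X <- as.matrix(df[, setdiff(colnames(df), fixed), drop = FALSE])
  storage.mode(X) <- "integer"
  catalog <- df[, c("start", "end", "exons")]
  catalog$exons <- as.character(catalog$exons)
  new_read_term_matrix(X, catalog, colnames(X), gene_id)
}
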
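#' Encode an exon composition as an integer
#'
#' An isoform is a binary vector over a gene's ordered exons (1 = exon
#' included). Reading the composition 5' to 3' as a binary numeral with
#' exon 1 as the most significant bit yields a unique nonnegative integer;
#' e.g. the composition (1,0,1) of a three-exon gene encodes to 5.
#'
#' @param composition Binary (0/1) vector of length E, not all zero.
#' @return Integer-valued numeric code in `[1, 2^E)`.
#' @export
encode_isoform <- function(composition) {
  composition <- check_composition(composition)
  E <- length(composition)
  if (E > 52L) stop("exact integer encoding supported up to 52 exons")
  sum(composition * 2^((E - 1L):0L))
}

#' Decode an integer isoform code to its exon composition
#'
#' @param code Integer code in `[1, 2^E)`.
#' @param E Number of exons of the gene.
#' @return Binary vector of length `E`; inverse of [encode_isoform()].
#' @export
decode_isoform <- function(code, E) {
  if (E < 1L || E > 52L) stop("E must be in [1, 52]")
  if (length(code) != 1L || code < 1 || code >= 2^E || code != floor(code))
    stop("code out of range [1, 2^E)")
  as.integer(floor(code / 2^((E - 1L):0L)) %% 2)
}

check_composition <- function(composition) {
  composition <- as.integer(composition)
  if (length(composition) < 1L || anyNA(composition) ||
      !all(composition %in% c(0L, 1L)))
    stop("composition must be a binary vector of length >= 1")
  if (!any(composition == 1L))
    stop("invalid isoform: all-zero composition")
  composition
}

#' Is a read term compatible with an isoform?
#'
#' A read term (set of covered exon indices) is compatible with an isoform
#' iff every covered exon is included in the isoform and every exon lying
#' strictly between consecutive covered exons is excluded (the read's
#' junctions must be reproduced exactly). Exons outside the term's span are
#' unconstrained.
#'
#' @param term_exons Strictly increasing vector of covered exon indices.
#' @param composition Binary composition vector of the isoform.
#' @return Logical scalar.
#' @export
compatibility <- function(term_exons, composition) {
  composition <- check_composition(composition)
  term_exons <- as.integer(term_exons)
  if (length(term_exons) < 1L || is.unsorted(term_exons, strictly = TRUE))
    stop("term exon set must be non-empty and strictly increasing")
  if (max(term_exons) > length(composition))
    stop("term exon index exceeds gene exon count")
  if (!all(composition[term_exons] == 1L)) return(FALSE)
  gaps <- setdiff(seq(min(term_exons), max(term_exons)), term_exons)
  all(composition[gaps] == 0L)
}

## K x V logical compatibility matrix for a catalog (K x E binary matrix)
## against a list of term exon-index vectors.
compat_matrix <- function(catalog, term_exons_list) {
  catalog <- as_catalog(catalog)
  K <- nrow(catalog)
  V <- length(term_exons_list)
  b <- matrix(FALSE, K, V)
  for (v in seq_len(V)) {
    te <- as.integer(term_exons_list[[v]])
    gaps <- setdiff(seq(min(te), max(te)), te)
    inc <- if (length(te) == 1L) catalog[, te] == 1L else
      rowSums(catalog[, te, drop = FALSE]) == length(te)
    exc <- if (length(gaps) == 0L) rep(TRUE, K) else
      rowSums(catalog[, gaps, drop = FALSE]) == 0L
    b[, v] <- inc & exc
  }
  b
}

## coerce catalog input (matrix, vector, or list of compositions) to a
## K x E binary matrix
as_catalog <- function(x, E = NULL) {
  if (is.list(x)) x <- do.call(rbind, lapply(x, as.integer))
  if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1L)
  x <- matrix(as.integer(x), nrow = nrow(x))
  if (!is.null(E) && ncol(x) != E) stop("composition length does not match E")
  x
}

## Union composition of a set of read terms: exactly the exons covered by
## some term are included (truncation-style candidate isoforms).
union_composition <- function(term_exons_list, E) {
  comp <- rep(0L, E)
  comp[sort(unique(unlist(term_exons_list)))] <- 1L
  comp
}

## Smallest composition consistent with a set of read terms: the union of
## their covered exons is included; an exon strictly inside some term's span
## is excluded when every term spanning it skips it; all other exons are
## included (unconstrained positions default to inclusion).
closure_from_terms <- function(term_exons_list, E) {
  comp <- rep(1L, E)
  covered <- sort(unique(unlist(term_exons_list)))
  for (i in seq_len(E)) {
    if (i %in% covered) next
    spanning <- Filter(function(te) min(te) < i && max(te) > i, term_exons_list)
    if (length(spanning) > 0L && all(vapply(spanning, function(te)
      !(i %in% te), logical(1))))
      comp[i] <- 0L
  }
  comp
}

#' Exonic length of an isoform (bp)
#' @param gene A [gene_model()].
#' @param composition Binary composition vector over the gene's exons.
#' @export
isoform_length <- function(gene, composition) {
  composition <- check_composition(composition)
  if (length(composition) != gene$E) stop("composition length != E")
  sum(exon_lengths(gene)[composition == 1L])
}

## gene model restricted to the included exons of a composition; retains a
## map from sub-gene exon index to original exon index
isoform_subgene <- function(gene, composition) {
  composition <- check_composition(composition)
  keep <- which(composition == 1L)
  ex <- gene$exons[keep, , drop = FALSE]
  sub <- structure(list(gene_id = gene$gene_id, exons = ex,
                        E = length(keep), strand = gene$strand,
                        chrom = gene$chrom),
                   class = "gene_model")
  attr(sub, "exon_map") <- keep
  sub
}
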
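#' Hamming distance between exon compositions
#'
#' Counts the number of mismatched exons between two binary compositions
#' of equal length.
#'
#' @param a,b Binary vectors of equal length.
#' @return Integer distance.
#' @export
hamming <- function(a, b) {
  if (length(a) != length(b)) stop("compositions differ in length")
  sum(as.integer(a) != as.integer(b))
}

#' Match inferred isoforms to true isoforms
#'
#' Solves the maximum-cardinality minimum-weight bipartite assignment
#' between inferred and true isoform sets under Hamming distance, via
#' the Hungarian algorithm (O(I^3)). Unequal set sizes are handled by
#' padding the smaller side with zero-weight dummy partners, which carry
#' no classification weight: inferred isoforms assigned to dummies are
#' unmatched (false positives at every threshold) and unassigned truths
#' are false negatives. Both inputs are sorted lexicographically first so
#' ties among equal-weight matchings resolve deterministically.
#'
#' @param inferred,truth K x E binary matrices (or lists of composition
#'   vectors) over the same exon count E. Either may be empty (0 rows).
#' @return An object of class `isoform_matching`: `pairs` (data.frame
#'   `inferred`, `truth`, `distance` of matched row indices),
#'   `unmatched_inferred`, `unmatched_truth` (row indices), objective
#'   `M`, plus the sorted `inferred` and `truth` matrices and `E`.
#' @export
match_isoforms <- function(inferred, truth) {
  E <- NULL
  norm <- function(x) {
    if (is.list(x)) x <- do.call(rbind, lapply(x, as.integer))
    if (is.null(x)) x <- matrix(integer(0), 0L, 0L)
    if (is.null(dim(x))) x <- matrix(as.integer(x), nrow = 1L)
    x
  }
  inferred <- norm(inferred)
  truth <- norm(truth)
  if (nrow(inferred) > 0L && nrow(truth) > 0L &&
      ncol(inferred) != ncol(truth))
    stop("isoform sets are over different exon counts")
  E <- max(ncol(inferred), ncol(truth))
  lex_order <- function(x) {
    if (nrow(x) == 0L) return(integer(0))
    do.call(order, as.data.frame(x))
  }
  inferred <- inferred[lex_order(inferred), , drop = FALSE]
  truth <- truth[lex_order(truth), , drop = FALSE]
  KC <- nrow(inferred)
  KT <- nrow(truth)
  pairs <- data.frame(inferred = integer(0), truth = integer(0),
                      distance = integer(0))
  un_inf <- seq_len(KC)
  un_tru <- seq_len(KT)
  if (KC > 0L && KT > 0L) {
    d <- matrix(0L, KC, KT)
    for (k in seq_len(KC)) for (l in seq_len(KT))
      d[k, l] <- hamming(inferred[k, ], truth[l, ])
    n <- max(KC, KT)
    dp <- matrix(0, n, n)            # dummy rows/columns carry zero weight
    dp[seq_len(KC), seq_len(KT)] <- d
    sol <- as.integer(clue::solve_LSAP(dp))
    k_idx <- seq_len(KC)
    l_idx <- sol[k_idx]
    real <- l_idx <= KT
    pairs <- data.frame(inferred = k_idx[real], truth = l_idx[real],
                        distance = d[cbind(k_idx[real], l_idx[real])])
    un_inf <- setdiff(seq_len(KC), pairs$inferred)
    un_tru <- setdiff(seq_len(KT), pairs$truth)
  }
  structure(list(pairs = pairs, unmatched_inferred = un_inf,
                 unmatched_truth = un_tru, M = sum(pairs$distance),
                 inferred = inferred, truth = truth, E = E),
            class = "isoform_matching")
}

#' @export
print.isoform_matching <- function(x, ...) {
  cat(sprintf("isoform_matching: %d pair%s (M = %d), %d unmatched inferred, %d unmatched truth\n",
              nrow(x$pairs), if (nrow(x$pairs) == 1L) "" else "s", x$M,
              length(x$unmatched_inferred), length(x$unmatched_truth)))
  invisible(x)
}

#' Precision and recall at a partial-matching threshold
#'
#' A matched pair with Hamming distance `d <= p * E` is a p-partial true
#' positive; matched pairs above the threshold and unmatched inferred
#' isoforms are p-false positives; true isoforms not covered by a p-true
#' positive are p-false negatives. `p = 0` reproduces exact matching.
#' Undefined values (zero denominators) are returned as `NA` with an
#' `undefined` attribute.
#'
#' @param result An `isoform_matching`.
#' @param p Threshold in `[0, 1]`.
#' @param E Exon count (defaults to the matching's).
#' @return Named vector `c(precision =, recall =)` with attributes `TP`,
#'   `FP`, `FN`.
#' @export
precision_recall <- function(result, p = 0, E = result$E) {
  stopifnot(p >= 0, p <= 1)
  tp <- sum(result$pairs$distance <= p * E)
  fp <- sum(result$pairs$distance > p * E) + length(result$unmatched_inferred)
  fn <- nrow(result$truth) - tp
  prec <- if (tp + fp == 0L) NA_real_ else tp / (tp + fp)
  rec <- if (tp + fn == 0L) NA_real_ else tp / (tp + fn)
  out <- c(precision = prec, recall = rec)
  attr(out, "TP") <- tp
  attr(out, "FP") <- fp
  attr(out, "FN") <- fn
  attr(out, "undefined") <- c(precision = tp + fp == 0L,
                              recall = tp + fn == 0L)
  out
}

#' Base-level coverage of matched isoforms
#'
#' For each matched pair, the fraction of the true isoform's exonic
#' bases that are present in the inferred isoform's exons; aggregated as
#' the length-weighted mean over pairs (weights = true isoform exonic
#' lengths). An inferred superset of the truth scores 1 (this measures
#' coverage, not precision).
#'
#' @param result An `isoform_matching`.
#' @param gene The shared [gene_model()] supplying exon lengths.
#' @return Proportion in `[0, 1]` (`NaN` when there are no pairs).
#' @export
base_coverage <- function(result, gene) {
  el <- exon_lengths(gene)
  if (nrow(result$pairs) == 0L) return(NaN)
  cov <- num <- numeric(nrow(result$pairs))
  for (i in seq_len(nrow(result$pairs))) {
    tr <- result$truth[result$pairs$truth[i], ]
    inf <- result$inferred[result$pairs$inferred[i], ]
    tlen <- sum(el[tr == 1L])
    num[i] <- sum(el[tr == 1L & inf == 1L])
    cov[i] <- tlen
  }
  sum(num) / sum(cov)
}

#' Score an inferred isoform set against truth
#'
#' Convenience wrapper reporting exact and p-partial precision/recall
#' plus base coverage for one gene.
#'
#' @param inferred,truth Binary composition matrices.
#' @param gene The shared [gene_model()].
#' @param p Partial-match threshold.
#' @return One-row data.frame with `precision`, `recall`,
#'   `p_precision`, `p_recall`, `base_coverage`, `M`.
#' @export
evaluate_isoforms <- function(inferred, truth, gene, p = 0.1) {
  mr <- match_isoforms(inferred, truth)
  ex <- precision_recall(mr, 0)
  px <- precision_recall(mr, p)
  data.frame(precision = ex[["precision"]], recall = ex[["recall"]],
             p_precision = px[["precision"]], p_recall = px[["recall"]],
             base_coverage = base_coverage(mr, gene), M = mr$M)
}
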
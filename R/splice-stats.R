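#' Filter a transcript-ratio matrix
#'
#' Applies the standard pre-test filters to one gene's per-sample
#' transcript ratios: transcripts whose ratio is constant at 0 or at 1
#' across all samples are discarded (such transcripts carry no splicing
#' signal and often reflect false junctions), as are transcripts with
#' nonzero ratio in fewer than `min_frac` of the samples. Genes left
#' with a single transcript, or with fewer than `min_exons` exons when
#' an exon count is supplied, are dropped entirely (an empty matrix is
#' returned).
#'
#' @param ratios n x T matrix: samples in rows, transcripts in columns.
#' @param min_frac Minimum fraction of samples with nonzero ratio
#'   (default 0.1).
#' @param n_exons Optional exon count of the gene.
#' @param min_exons Minimum exon count (default 3).
#' @return The retained ratio matrix (possibly with 0 columns).
#' @export
filter_transcripts <- function(ratios, min_frac = 0.1, n_exons = NULL,
                               min_exons = 3L) {
  ratios <- as.matrix(ratios)
  if (!is.null(n_exons) && n_exons < min_exons)
    return(ratios[, integer(0), drop = FALSE])
  keep <- vapply(seq_len(ncol(ratios)), function(t) {
    x <- ratios[, t]
    x <- x[!is.na(x)]
    if (length(x) == 0L) return(FALSE)
    if (all(x == 0) || all(x == 1)) return(FALSE)
    mean(x > 0) >= min_frac
  }, logical(1))
  out <- ratios[, keep, drop = FALSE]
  if (ncol(out) < 2L) out <- out[, integer(0), drop = FALSE]
  out
}

#' Maximum likelihood estimation for the Dirichlet distribution
#'
#' Fixed-point iteration (with inverse-digamma updates) to the Dirichlet
#' MLE from a matrix of simplex observations, started from the
#' method-of-moments estimate. Zero components are clamped to a small
#' floor (default 1e-6) and rows renormalised before taking logs, since
#' the Dirichlet support excludes exact zeros.
#'
#' @param x n x d matrix of simplex rows (n >= 2, d >= 2).
#' @param floor Clamping floor for zero components.
#' @param tol Convergence tolerance on the log-likelihood gradient norm.
#' @param max_iter Iteration cap.
#' @return Numeric vector of concentration estimates with attributes
#'   `loglik` and `converged`; samples that are all identical raise a
#'   degeneracy error (the MLE diverges).
#' @export
dirichlet_mle <- function(x, floor = 1e-6, tol = 1e-8, max_iter = 1000L) {
  x <- as.matrix(x)
  n <- nrow(x)
  d <- ncol(x)
  if (n < 2L) stop("need >= 2 samples for a Dirichlet MLE")
  if (d < 2L) stop("need dimension >= 2")
  x <- pmax(x, floor)
  x <- x / rowSums(x)
  if (all(apply(x, 2L, function(col) max(col) - min(col)) < 1e-12))
    stop("degenerate sample: all observations identical (MLE diverges)")
  logp <- colMeans(log(x))
  ## method-of-moments start
  m1 <- colMeans(x)
  m2 <- mean(x[, 1L]^2)
  s0 <- (m1[1L] - m2) / max(m2 - m1[1L]^2, 1e-12)
  a <- pmax(m1 * max(s0, 1e-3), 1e-6)
  conv <- FALSE
  for (it in seq_len(max_iter)) {
    a_new <- inv_digamma(digamma(sum(a)) + logp)
    a_new <- pmax(a_new, 1e-10)
    g <- digamma(sum(a_new)) + logp - digamma(a_new)
    a <- a_new
    if (sqrt(sum(g^2)) < tol) { conv <- TRUE; break }
  }
  out <- as.numeric(a)
  attr(out, "loglik") <- dirichlet_loglik(out, x)
  attr(out, "converged") <- conv
  out
}

## Newton inversion of the digamma function (Minka's initialisation)
inv_digamma <- function(y) {
  x <- ifelse(y >= -2.22, exp(y) + 0.5, -1 / (y - digamma(1)))
  for (i in 1:8) x <- x - (digamma(x) - y) / trigamma(x)
  x
}

dirichlet_loglik <- function(a, x) {
  n <- nrow(x)
  n * (lgamma(sum(a)) - sum(lgamma(a))) + sum((a - 1) * colMeans(log(x)) * n)
}

#' Likelihood-ratio test for group-specific transcript ratios
#'
#' Tests whether per-sample transcript-ratio vectors differ between
#' groups (e.g. populations or sexes). The alternative fits one
#' Dirichlet distribution per group by maximum likelihood; the null
#' fits a single shared Dirichlet to the pooled samples. The statistic
#' `2 * (sum of group log-likelihoods - pooled log-likelihood)` is
#' referred to a chi-squared distribution with `(G - 1) * T` degrees of
#' freedom for G groups and T transcripts. Groups with fewer than two
#' samples are excluded with a warning; correction for testing many
#' genes (e.g. Bonferroni) is the caller's responsibility.
#'
#' @param ratios n x T matrix of simplex rows.
#' @param groups Length-n group labels.
#' @param floor Zero-clamping floor passed to [dirichlet_mle()].
#' @return List with `statistic`, `df`, `p_value`, and the per-group and
#'   pooled MLEs.
#' @export
lr_test <- function(ratios, groups, floor = 1e-6) {
  ratios <- as.matrix(ratios)
  groups <- as.factor(groups)
  stopifnot(nrow(ratios) == length(groups))
  sizes <- table(groups)
  small <- names(sizes)[sizes < 2L]
  if (length(small) > 0L) {
    warning("excluding group(s) with < 2 samples: ",
            paste(small, collapse = ", "))
    keep <- !groups %in% small
    ratios <- ratios[keep, , drop = FALSE]
    groups <- droplevels(groups[keep])
  }
  G <- nlevels(groups)
  if (G < 2L) stop("need >= 2 usable groups")
  TT <- ncol(ratios)
  fits <- lapply(levels(groups), function(g)
    dirichlet_mle(ratios[groups == g, , drop = FALSE], floor = floor))
  names(fits) <- levels(groups)
  pooled <- dirichlet_mle(ratios, floor = floor)
  ll_alt <- sum(vapply(fits, attr, numeric(1), "loglik"))
  ll_null <- attr(pooled, "loglik")
  stat <- max(0, 2 * (ll_alt - ll_null))
  df <- (G - 1L) * TT
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE),
       group_mle = fits, pooled_mle = pooled)
}

#' Is a variant population-specific?
#'
#' A variant is population-specific when some allele's count in some
#' population exceeds fraction `t` of that allele's total count across
#' populations (strict inequality). Alleles with zero total count are
#' skipped.
#'
#' @param counts data.frame with columns `allele`, `population`,
#'   `count` for one variant.
#' @param t Population threshold in `[0, 1)`.
#' @return Logical scalar.
#' @export
population_specific <- function(counts, t) {
  stopifnot(t >= 0, t < 1)
  for (a in unique(counts$allele)) {
    rows <- counts[counts$allele == a, , drop = FALSE]
    total <- sum(rows$count)
    if (total == 0) next
    if (any(rows$count / total > t)) return(TRUE)
  }
  FALSE
}

#' Hypergeometric enrichment of population-specific alleles
#'
#' Counts population-specific variants (per [population_specific()])
#' with minor allele frequency at least `maf_min` in a selected gene
#' set versus a disjoint background set, and returns the hypergeometric
#' upper-tail probability of observing at least the selected count:
#' drawing `n = |selected|` variants from an urn of `N` variants of
#' which `K` are population-specific. Variant tables are expected to be
#' pre-pruned for linkage disequilibrium by the caller.
#'
#' @param selected,background data.frames with columns `variant`,
#'   `allele`, `population`, `count` and optionally `maf`.
#' @param t Population-specificity threshold.
#' @param maf_min Minimum minor allele frequency (applied when a `maf`
#'   column is present).
#' @return List with `p_value` and the urn counts `k`, `K`, `n`, `N`.
#' @export
enrichment_test <- function(selected, background, t, maf_min = 0) {
  if (nrow(background) == 0L) stop("empty background set")
  if (length(intersect(unique(selected$variant),
                       unique(background$variant))) > 0L)
    stop("selected and background variant sets must be disjoint")
  spec_count <- function(tab) {
    if ("maf" %in% colnames(tab)) tab <- tab[tab$maf >= maf_min, , drop = FALSE]
    vs <- unique(tab$variant)
    spec <- vapply(vs, function(v)
      population_specific(tab[tab$variant == v, , drop = FALSE], t),
      logical(1))
    c(total = length(vs), specific = sum(spec))
  }
  s <- spec_count(selected)
  b <- spec_count(background)
  N <- s[["total"]] + b[["total"]]
  K <- s[["specific"]] + b[["specific"]]
  n <- s[["total"]]
  k <- s[["specific"]]
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  list(p_value = p, k = k, K = K, n = n, N = N)
}
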
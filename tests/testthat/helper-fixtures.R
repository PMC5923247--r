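# Shared fixtures and independent oracles used across the suite.

# five 200 bp exons separated by 100 bp introns
fixture_gene <- function(E = 5L, exon_length = 200L, intron = 100L) {
  starts <- 1L + (seq_len(E) - 1L) * (exon_length + intron)
  gene_model(paste0("fixgene", E), starts, starts + exon_length)
}

# BRCA2-like first two exons from the worked example
fixture_brca2 <- function() {
  gene_model("BRCA2", c(1L, 2617L), c(67L, 2865L))
}

# Oracle: a read term is realisable from an isoform iff its exon set is a
# contiguous run of the isoform's included exons (derived by walking the
# spliced transcript, independent of the compatibility rule).
oracle_compatible <- function(term_exons, composition) {
  incl <- which(composition == 1L)
  if (!all(term_exons %in% incl)) return(FALSE)
  idx <- match(term_exons, incl)
  length(idx) >= 1L && all(diff(idx) == 1L)
}

# Oracle: exhaustive maximum-cardinality minimum-weight matching between
# two isoform sets (enumerates all injections of the smaller side).
oracle_match_weight <- function(inferred, truth) {
  KC <- nrow(inferred)
  KT <- nrow(truth)
  if (KC == 0L || KT == 0L) return(0L)
  d <- matrix(0L, KC, KT)
  for (k in seq_len(KC)) for (l in seq_len(KT))
    d[k, l] <- sum(inferred[k, ] != truth[l, ])
  small <- min(KC, KT)
  big <- max(KC, KT)
  best <- Inf
  combos <- utils::combn(big, small, simplify = FALSE)
  perms <- perm_all(small)
  for (sub in combos) for (p in perms) {
    w <- if (KC <= KT) sum(d[cbind(seq_len(small), sub[p])]) else
      sum(d[cbind(sub[p], seq_len(small))])
    if (w < best) best <- w
  }
  best
}

perm_all <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(n)) {
    for (p in perm_all(n - 1L)) {
      rest <- setdiff(seq_len(n), i)
      out[[length(out) + 1L]] <- c(i, rest[p])
    }
  }
  out
}

# Oracle: data log-likelihood by exhaustive enumeration over all K^n read
# assignment vectors (one gene-sample, explicit emission matrix).
oracle_loglik_enum <- function(term_ids, psi, P) {
  n <- length(term_ids)
  K <- length(psi)
  total <- 0
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), n)))
  for (r in seq_len(nrow(grid))) {
    z <- grid[r, ]
    total <- total + prod(psi[z]) * prod(P[cbind(z, term_ids)])
  }
  log(total)
}
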
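#' Configuration for gene-level short-read simulation
#'
#' Describes a desk-scale multi-isoform gene simulation: per-sample
#' isoform proportions are Dirichlet with symmetric concentration
#' `alpha` (default 1), read starts are 5'-biased, and the per-sample
#' read depth follows a coverage target.
#'
#' @param gene A [gene_model()] template, or `NULL` to build one with
#'   `E` exons of `exon_length` bp separated by `intron_length` bp.
#' @param E,exon_length,intron_length Template geometry used when `gene`
#'   is `NULL`.
#' @param isoforms K x E binary matrix of true compositions, or `NULL`
#'   to draw `n_isoforms` distinct random compositions (full-length
#'   isoform always included first).
#' @param n_isoforms Number of true isoforms when `isoforms` is `NULL`.
#' @param alpha Per-sample Dirichlet concentration (default 1, the
#'   standard uninformative setting for isoform-proportion simulation).
#' @param coverage Mean per-sample coverage target of the longest
#'   transcript; reads per sample = `coverage * span / read_length`.
#' @param read_length Read length in bp.
#' @param m Number of samples.
#' @param bias 5'-bias strength `>= 0`: read starts are drawn with
#'   density proportional to a gamma(shape 1, rate `bias`) density in
#'   relative transcript position, i.e. `exp(-bias * u)`; 0 gives
#'   uniform starts.
#' @param seed Integer seed.
#' @param max_resample Attempts to re-draw a gene-sample pool failing
#'   the coverage / exon-support filters.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(gene = NULL, E = 5L, exon_length = 200L,
                       intron_length = 100L, isoforms = NULL,
                       n_isoforms = 2L, alpha = 1, coverage = 5,
                       read_length = 100L, m = 20L, bias = 0,
                       seed = 1L, max_resample = 20L) {
  stopifnot(coverage > 0, read_length >= 1L, m >= 1L, bias >= 0,
            alpha > 0)
  if (is.null(gene)) {
    starts <- 1L + (seq_len(E) - 1L) * (exon_length + intron_length)
    gene <- gene_model("simgene", starts, starts + exon_length)
  }
  structure(list(gene = gene, isoforms = isoforms,
                 n_isoforms = as.integer(n_isoforms), alpha = alpha,
                 coverage = coverage, read_length = as.integer(read_length),
                 m = as.integer(m), bias = bias, seed = as.integer(seed),
                 max_resample = as.integer(max_resample)),
            class = "sim_config")
}

## draw a transcript-relative start offset in [0, tmax] with 5' bias
biased_start <- function(n, tmax, bias) {
  if (tmax == 0L) return(rep(0L, n))
  if (bias == 0) return(sample.int(tmax + 1L, n, replace = TRUE) - 1L)
  u <- seq(0L, tmax)
  wts <- exp(-bias * u / (tmax + 1))
  sample(u, n, replace = TRUE, prob = wts)
}

#' Simulate short reads for a multi-isoform gene
#'
#' For each sample, isoform proportions are drawn from a symmetric
#' Dirichlet(`alpha`); each read picks an isoform from those proportions
#' and a 5'-biased start over the isoform's exonic coordinates, and is
#' converted to a read term. A simulated gene failing the standard
#' filters (pooled coverage below target, or some exon without any read)
#' is redrawn, and the resampling events are logged.
#'
#' @param cfg A [sim_config()].
#' @return A list with `reads` (data.frame `sample`, `isoform`, `start`,
#'   `end`, `exons`), `rtm` (the `read_term_matrix`), `truth` (list of
#'   `isoforms`, `psi`, `z_counts`), `gene`, and `resampled` (number of
#'   redraws).
#' @export
simulate_gene_reads <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  gene <- cfg$gene
  set.seed(cfg$seed)
  isoforms <- cfg$isoforms
  if (is.null(isoforms)) {
    comps <- list(rep(1L, gene$E))
    guard <- 0L
    while (length(comps) < cfg$n_isoforms && guard < 1000L) {
      cand <- stats::rbinom(gene$E, 1L, 0.6)
      guard <- guard + 1L
      if (!any(cand == 1L)) next
      if (isoform_length(gene, cand) < cfg$read_length) next
      if (any(vapply(comps, function(cc) all(cc == cand), logical(1)))) next
      comps[[length(comps) + 1L]] <- cand
    }
    isoforms <- as_catalog(comps, gene$E)
  } else {
    isoforms <- as_catalog(isoforms, gene$E)
  }
  K <- nrow(isoforms)
  lens <- vapply(seq_len(K), function(k)
    isoform_length(gene, isoforms[k, ]), numeric(1))
  if (any(lens < cfg$read_length))
    stop("config error: isoform shorter than the read length")
  subs <- lapply(seq_len(K), function(k) isoform_subgene(gene, isoforms[k, ]))
  n_reads <- max(1L, round(cfg$coverage * max(lens) / cfg$read_length))
  resampled <- 0L
  repeat {
    psi <- t(vapply(seq_len(cfg$m), function(j)
      rdirichlet1(rep(cfg$alpha, K)), numeric(K)))
    if (K == 1L) psi <- matrix(1, cfg$m, 1L)
    rows <- vector("list", cfg$m)
    zc <- matrix(0L, cfg$m, K)
    for (j in seq_len(cfg$m)) {
      z <- sample.int(K, n_reads, replace = TRUE, prob = psi[j, ])
      zc[j, ] <- tabulate(z, K)
      recs <- vector("list", n_reads)
      for (i in seq_len(n_reads)) {
        sub <- subs[[z[i]]]
        t0 <- biased_start(1L, transcript_span(sub) - cfg$read_length,
                           cfg$bias)
        tm <- read_to_term(tx_to_genomic(sub, t0), cfg$read_length, sub)
        recs[[i]] <- data.frame(
          sample = j, isoform = z[i], start = tm$start, end = tm$end,
          exons = paste(attr(sub, "exon_map")[tm$exons], collapse = ","))
      }
      rows[[j]] <- do.call(rbind, recs)
    }
    reads <- do.call(rbind, rows)
    ## filters: pooled mean coverage and at least one read in each exon
    covered_exons <- sort(unique(unlist(parse_exons(reads$exons))))
    used_exons <- sort(unique(which(colSums(isoforms) > 0)))
    mean_cov <- nrow(reads) * cfg$read_length /
      (cfg$m * max(lens))
    ok <- identical(covered_exons, used_exons) &&
      mean_cov >= cfg$coverage - cfg$read_length / max(lens)
    if (ok || resampled >= cfg$max_resample) break
    resampled <- resampled + 1L
  }
  per_sample <- split(reads[c("start", "end", "exons")], reads$sample)
  names(per_sample) <- paste0("sample", names(per_sample))
  rtm <- build_count_matrix(per_sample)
  list(reads = reads, rtm = rtm,
       truth = list(isoforms = isoforms, psi = psi, z_counts = zc),
       gene = gene, resampled = resampled)
}

#' Configuration for fragmenting long reads into short reads
#'
#' @param read_length Short-read length in bp (the study design used 50,
#'   100 and 200 bp).
#' @param span Target fraction of each long read's transcript span that
#'   the generated short reads must cover, in `(0, 1]`.
#' @param insert_mean,insert_sd Normal insert-size model between
#'   consecutive short reads (defaults 10 bp and 40 bp); negative draws
#'   are truncated to 0 (abutting reads) when placing reads, while the
#'   raw pre-truncation draws are recorded for diagnostics.
#' @param seed Integer seed.
#' @return An object of class `fragment_config`.
#' @export
fragment_config <- function(read_length = 100L, span = 1, insert_mean = 10,
                            insert_sd = 40, seed = 1L) {
  stopifnot(read_length >= 1L, span > 0, span <= 1)
  structure(list(read_length = as.integer(read_length), span = span,
                 insert_mean = insert_mean, insert_sd = insert_sd,
                 seed = as.integer(seed)),
            class = "fragment_config")
}

#' Fragment long reads into insert-separated short reads
#'
#' Walks each long-read alignment along the gene's exonic sequence,
#' emitting short reads separated by normally distributed insert sizes
#' (truncated at 0), in repeated passes with random phase until the
#' cumulative covered fraction of the long read's transcript span
#' reaches `cfg$span`. Positions are copied from the source alignment,
#' so any mapping bias in the long reads persists in the short reads.
#' Long reads shorter than the short-read length are skipped with a
#' warning.
#'
#' @param long_alignments data.frame with columns `qname`, `start`,
#'   `end`: half-open genomic spans of long reads, lying within the
#'   gene's exons.
#' @param gene A [gene_model()].
#' @param cfg A [fragment_config()].
#' @return data.frame of short reads (`qname`, `start`, `end`, `exons`)
#'   with attributes `inserts` (the raw pre-truncation normal draws) and
#'   `covered_fraction` (per long read).
#' @export
fragment_long_reads <- function(long_alignments, gene, cfg) {
  stopifnot(inherits(cfg, "fragment_config"))
  set.seed(cfg$seed)
  R <- cfg$read_length
  all_reads <- list()
  inserts <- numeric(0)
  covfrac <- numeric(0)
  for (i in seq_len(nrow(long_alignments))) {
    q <- long_alignments$qname[i]
    t0 <- genomic_to_tx(gene, long_alignments$start[i])
    t1 <- genomic_to_tx(gene, long_alignments$end[i] - 1L) + 1L
    if (is.na(t0) || is.na(t1)) {
      warning("long read ", q, " does not map within the gene's exons; skipped")
      next
    }
    S <- t1 - t0
    if (S < R) {
      warning("long read ", q, " shorter than the short-read length; skipped")
      next
    }
    covered <- rep(FALSE, S)
    passes <- 0L
    done <- FALSE
    repeat {
      pos <- if (passes == 0L) 0L else
        sample.int(max(1L, min(R, S - R + 1L)), 1L) - 1L
      while (pos + R <= S) {
        g0 <- tx_to_genomic(gene, t0 + pos)
        tm <- read_to_term(g0, R, gene)
        all_reads[[length(all_reads) + 1L]] <-
          data.frame(qname = q, start = tm$start, end = tm$end,
                     exons = paste(tm$exons, collapse = ","))
        covered[(pos + 1L):(pos + R)] <- TRUE
        if (mean(covered) >= cfg$span) { done <- TRUE; break }
        ins <- stats::rnorm(1L, cfg$insert_mean, cfg$insert_sd)
        inserts <- c(inserts, ins)
        pos <- pos + R + max(0L, round(ins))
      }
      passes <- passes + 1L
      if (done || passes > 50L) break
    }
    covfrac <- c(covfrac, mean(covered))
  }
  out <- if (length(all_reads)) do.call(rbind, all_reads) else
    data.frame(qname = character(), start = integer(), end = integer(),
               exons = character())
  rownames(out) <- NULL
  attr(out, "inserts") <- inserts
  attr(out, "covered_fraction") <- covfrac
  attr(out, "gene_id") <- gene$gene_id
  out
}

#' Sample from the insert-size model
#'
#' Raw (pre-truncation) normal insert-size draws as used between
#' consecutive fragmented short reads.
#'
#' @param n Number of draws.
#' @param cfg A [fragment_config()].
#' @param seed Optional seed (defaults to the config's).
#' @return Numeric vector of draws.
#' @export
sample_inserts <- function(n, cfg = fragment_config(), seed = cfg$seed) {
  set.seed(seed)
  stats::rnorm(n, cfg$insert_mean, cfg$insert_sd)
}
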
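#' Model hyperparameters
#'
#' Collects the hyperparameters of the hierarchical Dirichlet process
#' admixture over isoforms: `omega` (global DP concentration), `alpha`
#' (per-sample DP concentration), `r`/`s` (beta prior shapes on per-exon
#' read-term usage probabilities), `eta` (Dirichlet emission
#' pseudo-counts, scalar or length-V), `epsilon` (emission noise floor
#' shared across all read terms so every emission Dirichlet is defined),
#' and truncation levels `K_max` (global isoforms) and `L_max` (per-sample
#' isoform slots).
#'
#' @param omega,alpha,r,s,epsilon Positive scalars.
#' @param eta Positive scalar or vector of per-term pseudo-counts.
#' @param K_max,L_max Integer truncations, `K_max >= L_max >= 1`.
#' @return An object of class `hdp_hyper`.
#' @export
hyperparameters <- function(omega = 1, alpha = 1, r = 1, s = 1, eta = 1,
                            epsilon = 1e-3, K_max = 20L, L_max = 10L) {
  vals <- c(omega = omega, alpha = alpha, r = r, s = s,
            epsilon = epsilon)
  if (any(vals <= 0) || any(eta <= 0))
    stop("all hyperparameters must be strictly positive")
  if (K_max < L_max || L_max < 1L) stop("need K_max >= L_max >= 1")
  structure(list(omega = omega, alpha = alpha, r = r, s = s, eta = eta,
                 epsilon = epsilon, K_max = as.integer(K_max),
                 L_max = as.integer(L_max)),
            class = "hdp_hyper")
}

## Emission simplex per isoform: Dirichlet-mean over compatible terms with
## an additive epsilon/V floor renormalised over all V terms. Returns K x V.
emission_matrix <- function(catalog, term_exons_list, hyp) {
  catalog <- as_catalog(catalog)
  V <- length(term_exons_list)
  b <- compat_matrix(catalog, term_exons_list)
  eta <- rep_len(hyp$eta, V)
  P <- b * rep(eta, each = nrow(b)) + hyp$epsilon / V
  P / rowSums(P)
}

## Number of read terms of length `read_length` an isoform can emit, at
## one representative per (covered-exon window, start bin): the size of
## the isoform's full compatible-term space, observed or not. Used to
## normalise structural emissions so compositions are comparable even
## when part of their term space is unobserved.
count_compatible_terms <- function(gene, composition, read_length,
                                   bin = read_length) {
  sub <- isoform_subgene(gene, composition)
  tlen <- transcript_span(sub)
  if (tlen < read_length) return(0L)
  t_all <- 0L:(tlen - read_length)
  f_ex <- tx_to_exon(sub, t_all)
  l_ex <- tx_to_exon(sub, t_all + read_length - 1L)
  run <- cumsum(c(1L, diff(f_ex) != 0L | diff(l_ex) != 0L))
  sum(vapply(split(t_all, run), function(tt)
    length(unique(c(seq(tt[1L], tt[length(tt)], by = max(1L, bin)),
                    tt[length(tt)]))), numeric(1)))
}

#' Enumerate the read-term universe implied by a set of isoforms
#'
#' Walks reads of length `read_length` along each isoform's exonic
#' sequence at every start position, records the resulting read terms,
#' and thins them to one representative per (exon set, start bin). This
#' is the observation space used by [sample_dataset()] and by the
#' simulators.
#'
#' @param gene A [gene_model()].
#' @param isoforms K x E binary matrix (or list) of compositions.
#' @param read_length Read length in bp.
#' @param bin Start-position bin width (default `read_length`).
#' @return data.frame with columns `start`, `end`, `exons`.
#' @keywords internal
term_universe <- function(gene, isoforms, read_length, bin = read_length) {
  isoforms <- as_catalog(isoforms, gene$E)
  seen <- new.env(parent = emptyenv())
  rows <- list()
  for (k in seq_len(nrow(isoforms))) {
    sub <- isoform_subgene(gene, isoforms[k, ])
    emap <- attr(sub, "exon_map")
    tlen <- transcript_span(sub)
    if (tlen < read_length)
      stop("isoform shorter than read length")
    ## partition start offsets into runs sharing a covered-exon window,
    ## then thin each run to a bin grid (every junction window is kept)
    t_all <- 0L:(tlen - read_length)
    f_ex <- tx_to_exon(sub, t_all)
    l_ex <- tx_to_exon(sub, t_all + read_length - 1L)
    run <- cumsum(c(1L, diff(f_ex) != 0L | diff(l_ex) != 0L))
    starts <- unlist(lapply(split(t_all, run), function(tt)
      unique(c(seq(tt[1L], tt[length(tt)], by = max(1L, bin)),
               tt[length(tt)]))))
    for (t0 in starts) {
      g0 <- tx_to_genomic(sub, t0)
      tm <- read_to_term(g0, read_length, sub)
      ex <- emap[tm$exons]
      key <- term_key(tm$start, tm$end, paste(ex, collapse = ","))
      if (!is.null(seen[[key]])) next
      seen[[key]] <- TRUE
      rows[[length(rows) + 1L]] <-
        data.frame(start = tm$start, end = tm$end,
                   exons = paste(ex, collapse = ","))
    }
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$start, out$end, out$exons), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Exact log joint probability of the model
#'
#' Computes the log of prior times likelihood for explicit global and
#' per-sample states, with read-to-slot assignments marginalised
#' analytically: each read-term occurrence contributes the log of its
#' mixture probability over global isoforms. Emission distributions are
#' the per-isoform Dirichlet-mean simplexes over compatible terms with
#' the `epsilon` floor (see [hyperparameters()]).
#'
#' @param X A `read_term_matrix` (or plain V x m count matrix with a
#'   `catalog` attribute supplying `exons`).
#' @param global List with `isoforms` (K x E binary matrix), and
#'   optionally `weights` (length-K simplex of global isoform weights,
#'   default uniform) and `pi` (length-E exon usage probabilities).
#' @param samples List with `psi` (m x L matrix, rows simplexes) and `c`
#'   (m x L integer matrix mapping sample slots to global isoforms;
#'   default: L = K and `c[j, l] = l`).
#' @param hyp A [hyperparameters()].
#' @param include_prior If `FALSE`, return only the data log-likelihood.
#' @return Finite log-probability (scalar).
#' @export
log_joint <- function(X, global, samples, hyp = hyperparameters(),
                      include_prior = TRUE) {
  if (inherits(X, "read_term_matrix")) {
    exons <- parse_exons(X$catalog$exons)
    Xm <- X$X
  } else {
    Xm <- X
    exons <- parse_exons(attr(X, "catalog")$exons)
  }
  catalog <- as_catalog(global$isoforms)
  K <- nrow(catalog)
  m <- ncol(Xm)
  psi <- samples$psi
  if (is.null(dim(psi))) psi <- matrix(psi, nrow = m)
  if (any(abs(rowSums(psi) - 1) > 1e-6))
    stop("invalid state: psi rows must be simplexes")
  cmap <- samples$c
  if (is.null(cmap)) cmap <- matrix(rep(seq_len(K), each = m), m)
  L <- ncol(psi)
  ## effective per-sample mixture over global isoforms
  mix <- matrix(0, m, K)
  for (l in seq_len(L))
    for (j in seq_len(m))
      mix[j, cmap[j, l]] <- mix[j, cmap[j, l]] + psi[j, l]
  P <- emission_matrix(catalog, exons, hyp)
  probs <- mix %*% P                       # m x V mixture emission probs
  ll <- sum(t(Xm) * log(probs))
  if (!include_prior) return(ll)
  ## priors: global weights (symmetric Dirichlet proxy for the truncated
  ## stick prior), per-sample psi | alpha * weights, exon usage pi, and
  ## term usage b | pi
  w <- global$weights
  if (is.null(w)) w <- rep(1 / K, K)
  w <- pmax(w, 1e-12)
  ## truncated-DP plug-ins: global weights ~ Dir(omega/K), per-sample slot
  ## proportions ~ Dir(alpha/L), slot-to-isoform labels ~ Multinomial(w)
  lp <- lgamma(hyp$omega) - K * lgamma(hyp$omega / K) +
    sum((hyp$omega / K - 1) * log(w))
  lp <- lp + m * (lgamma(hyp$alpha) - L * lgamma(hyp$alpha / L)) +
    sum((hyp$alpha / L - 1) * log(pmax(psi, 1e-12)))
  lp <- lp + sum(log(w[cmap[, seq_len(L), drop = FALSE]]))
  pi_e <- global$pi
  if (is.null(pi_e)) pi_e <- rep(hyp$r / (hyp$r + hyp$s), gene_E_from(catalog))
  lp <- lp + sum(stats::dbeta(pmin(pmax(pi_e, 1e-9), 1 - 1e-9),
                              hyp$r, hyp$s, log = TRUE))
  bmat <- compat_matrix(catalog, exons)
  start_exon <- vapply(exons, `[`, integer(1), 1L)
  pv <- pmin(pmax(pi_e[start_exon], 1e-9), 1 - 1e-9)
  lp <- lp + sum(t(bmat) * log(pv) + t(!bmat) * log1p(-pv))
  ll + lp
}

gene_E_from <- function(catalog) ncol(catalog)

#' Simulate read-term data from the generative model
#'
#' Draws per-sample isoform proportions from a Dirichlet distribution
#' centred on the global isoform weights (symmetric with concentration
#' `hyp$alpha` when weights are uniform), assigns each read to an isoform
#' multinomially, and draws its read term from that isoform's emission
#' simplex over compatible terms. Returns the observed count matrix plus
#' the latent truth (proportions, realised read assignments, catalog) for
#' recovery experiments.
#'
#' @param gene A [gene_model()].
#' @param true_isoforms K x E binary matrix (or list) of compositions.
#' @param hyp A [hyperparameters()]; `alpha` scales the per-sample
#'   Dirichlet concentration and `epsilon`/`eta` shape the emissions.
#' @param m Number of samples.
#' @param reads_per_sample Reads drawn per sample (may be a scalar or a
#'   length-m vector).
#' @param seed Integer seed; identical seeds give identical data.
#' @param read_length Read length used to enumerate the term universe.
#' @param global_weights Optional length-K simplex (default uniform).
#' @return A list with `rtm` (a `read_term_matrix`) and `truth` (list of
#'   `isoforms`, `psi` drawn proportions, `z_counts` realised per-isoform
#'   read counts, `global_weights`).
#' @export
sample_dataset <- function(gene, true_isoforms, hyp = hyperparameters(),
                           m, reads_per_sample, seed,
                           read_length = 100L, global_weights = NULL) {
  isoforms <- as_catalog(true_isoforms, gene$E)
  K <- nrow(isoforms)
  if (K < 1L) stop("need at least one true isoform")
  set.seed(as.integer(seed))
  uni <- term_universe(gene, isoforms, read_length)
  exons <- parse_exons(uni$exons)
  P <- emission_matrix(isoforms, exons, hyp)
  w <- if (is.null(global_weights)) rep(1 / K, K) else global_weights / sum(global_weights)
  conc <- hyp$alpha * K * w
  n <- rep_len(reads_per_sample, m)
  V <- nrow(uni)
  X <- matrix(0L, V, m, dimnames = list(NULL, paste0("sample", seq_len(m))))
  psi <- matrix(0, m, K)
  zc <- matrix(0L, m, K)
  for (j in seq_len(m)) {
    psi[j, ] <- rdirichlet1(conc)
    if (n[j] == 0L) next
    z <- sample.int(K, n[j], replace = TRUE, prob = psi[j, ])
    zc[j, ] <- tabulate(z, K)
    for (k in which(zc[j, ] > 0L)) {
      v <- sample.int(V, zc[j, k], replace = TRUE, prob = P[k, ])
      tv <- tabulate(v, V)
      X[, j] <- X[, j] + tv
    }
  }
  rtm <- new_read_term_matrix(X, uni, colnames(X), gene$gene_id)
  list(rtm = rtm,
       truth = list(isoforms = isoforms, psi = psi, z_counts = zc,
                    global_weights = w, read_length = read_length))
}

## one Dirichlet draw via gamma variates
rdirichlet1 <- function(conc) {
  g <- stats::rgamma(length(conc), shape = conc, rate = 1)
  if (sum(g) <= 0) { g <- rep(1, length(conc)) }
  g / sum(g)
}
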
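#' Configuration for stochastic variational inference
#'
#' @param forgetting,delay Robbins-Monro step-size schedule
#'   `rho_t = (t + delay)^(-forgetting)`; `forgetting` in (0.5, 1].
#' @param batch_size Samples per stochastic update (capped at m).
#' @param move_period Iterations between merge-propose-reduce catalog
#'   moves.
#' @param poor_map_threshold Reads whose best posterior mapping
#'   probability over current isoforms falls below this are candidates
#'   for isoform proposals.
#' @param reduce_threshold An isoform is removed when no read in any
#'   sample maps to it with probability above this.
#' @param tol Relative-change convergence tolerance on the objective.
#' @param max_iter Maximum SVI iterations per restart.
#' @param restarts Number of random restarts; the restart with the
#'   highest final joint probability is returned.
#' @param n_local Coordinate-ascent sweeps per sample per visit.
#' @param seed Integer seed controlling all randomness.
#' @return An object of class `fit_config`.
#' @export
fit_config <- function(forgetting = 0.6, delay = 1, batch_size = 16L,
                       move_period = 30L, poor_map_threshold = 0.5,
                       reduce_threshold = 0.01, tol = 1e-5,
                       max_iter = 300L, restarts = 5L, n_local = 5L,
                       seed = 1L) {
  stopifnot(move_period >= 1L, poor_map_threshold > 0,
            poor_map_threshold < 1, reduce_threshold > 0,
            reduce_threshold < 1, restarts >= 1L)
  structure(list(forgetting = forgetting, delay = delay,
                 batch_size = as.integer(batch_size),
                 move_period = as.integer(move_period),
                 poor_map_threshold = poor_map_threshold,
                 reduce_threshold = reduce_threshold, tol = tol,
                 max_iter = as.integer(max_iter),
                 restarts = as.integer(restarts),
                 n_local = as.integer(n_local),
                 seed = as.integer(seed)),
            class = "fit_config")
}

## -- stick-breaking expectations -------------------------------------------
## g1, g2: Beta parameters for sticks 1..K-1 (element K is the remainder).
stick_elogw <- function(g1, g2) {
  K <- length(g1)
  if (K == 1L) return(0)
  i <- seq_len(K - 1L)
  elogv <- c(digamma(g1[i]) - digamma(g1[i] + g2[i]), 0)
  elog1mv <- digamma(g2[i]) - digamma(g1[i] + g2[i])
  elogv + c(0, cumsum(elog1mv))
}

stick_ew <- function(g1, g2) {
  K <- length(g1)
  if (K == 1L) return(1)
  i <- seq_len(K - 1L)
  ev <- c(g1[i] / (g1[i] + g2[i]), 1)
  w <- ev * cumprod(c(1, 1 - ev[i]))
  w / sum(w)
}

row_softmax <- function(logp) {
  mx <- logp[cbind(seq_len(nrow(logp)), max.col(logp, ties.method = "first"))]
  p <- exp(logp - mx)
  p / rowSums(p)
}

## -- state construction ----------------------------------------------------

svi_init <- function(rtm, gene, hyp, cfg) {
  X <- rtm$X
  V <- nrow(X)
  m <- ncol(X)
  term_exons <- parse_exons(rtm$catalog$exons)
  ## seed catalog: full-length isoform plus, for every distinct observed
  ## exon set (ordered by count support), both its inclusion closure
  ## (unconstrained exons included) and its span-only composition
  ## (exactly the covered exons); capped at K_max
  tot <- rowSums(X)
  comps <- list(rep(1L, gene$E))
  sets <- rtm$catalog$exons[order(-tot)]
  for (s in unique(sets[tot[order(-tot)] > 0])) {
    te <- parse_exons(s)
    comps[[length(comps) + 1L]] <- closure_from_terms(te, gene$E)
    comps[[length(comps) + 1L]] <- union_composition(te, gene$E)
  }
  catalog <- as_catalog(comps, gene$E)
  codes <- apply(catalog, 1L, encode_isoform)
  keep <- !duplicated(codes)
  catalog <- catalog[keep, , drop = FALSE]
  codes <- codes[keep]
  if (nrow(catalog) > hyp$K_max) {
    catalog <- catalog[seq_len(hyp$K_max), , drop = FALSE]
    codes <- codes[seq_len(hyp$K_max)]
  }
  ## working read length, used to size each composition's full
  ## compatible-term space: the median exonic extent of observed terms
  exlen <- vapply(seq_len(V), function(v) {
    ex <- gene$exons[term_exons[[v]], , drop = FALSE]
    sum(pmin(ex$end, rtm$catalog$end[v]) -
          pmax(ex$start, rtm$catalog$start[v]))
  }, numeric(1))
  read_len <- max(1L, as.integer(round(stats::median(exlen))))
  state <- structure(list(gene = gene, hyp = hyp, cfg = cfg,
                          term_exons = term_exons, catalog = rtm$catalog,
                          V = V, m = m, L = hyp$L_max,
                          read_len = read_len,
                          isoforms = catalog, codes = codes,
                          tried = numeric(0), iter = 0L,
                          trace = list(), converged = FALSE),
                     class = "svi_state")
  svi_reinit(state, keep_tried = TRUE)
}

## Structural emission rows over the observed catalog: compatible terms
## carry eta mass and every observed term the epsilon/V floor, while the
## normaliser spans the isoform's FULL compatible-term space (n_total per
## isoform, observed or not) so that compositions whose term space is
## largely unobserved do not have their floor mass inflated into a
## uniform emission.
structural_emission <- function(b, eta_v, epsilon, n_total) {
  K <- nrow(b)
  V <- ncol(b)
  num <- b * rep(eta_v, each = K) + epsilon / V
  num / (pmax(n_total, 1) * mean(eta_v) + epsilon)
}

catalog_n_total <- function(state, isoforms = state$isoforms) {
  vapply(seq_len(nrow(isoforms)), function(k)
    count_compatible_terms(state$gene, isoforms[k, ], state$read_len),
    numeric(1))
}

## (re)initialise all variational parameters for the current catalog
svi_reinit <- function(state, keep_tried = TRUE) {
  hyp <- state$hyp
  K <- nrow(state$isoforms)
  V <- state$V
  m <- state$m
  L <- state$L
  b <- compat_matrix(state$isoforms, state$term_exons)
  eta <- rep_len(hyp$eta, V)
  prior <- b * rep(eta, each = K) + hyp$epsilon / V
  state$b <- b
  state$prior <- prior
  ## emissions are structural: the Dirichlet-mean implied by the
  ## composition (eta-weighted compatible terms with the epsilon floor)
  state$lambda <- prior
  state$n_total <- catalog_n_total(state)
  state$ga <- rep(1, K)
  state$gb <- rep(hyp$omega, K)
  state$phi <- lapply(seq_len(m), function(j)
    row_softmax(matrix(stats::runif(L * K, 0, 0.1), L, K)))
  state$zeta <- lapply(seq_len(m), function(j) matrix(1 / L, V, L))
  state$s1 <- matrix(1, m, L)
  state$s2 <- matrix(hyp$alpha, m, L)
  state$psi_bar <- matrix(1 / K, m, K)
  state$beta_bar <- structural_emission(b, eta, hyp$epsilon, state$n_total)
  state
}

## coordinate ascent on one sample's local parameters; returns the state
## with updated phi/zeta/sticks and the sufficient stats for the global
## update
svi_local <- function(state, j, x, elogbeta, elogw, n_inner) {
  obs <- which(x > 0L)
  L <- state$L
  K <- nrow(state$isoforms)
  if (length(obs) == 0L) {
    return(list(state = state, lstat = matrix(0, K, state$V),
                nk = rep(0, K)))
  }
  xo <- x[obs]
  ze <- state$zeta[[j]][obs, , drop = FALSE]
  ph <- state$phi[[j]]
  g1 <- state$s1[j, ]
  g2 <- state$s2[j, ]
  eb <- elogbeta[, obs, drop = FALSE]            # K x obs
  teb <- t(eb)
  for (it in seq_len(n_inner)) {
    elogpsi <- stick_elogw(g1, g2)
    ze <- row_softmax(t(ph %*% eb + elogpsi))   # col-major broadcast
    nl <- colSums(ze * xo)
    g1 <- 1 + nl
    g2 <- state$hyp$alpha + c(rev(cumsum(rev(nl)))[-1L], 0)
    ph <- row_softmax(t(ze * xo) %*% teb + rep(elogw, each = L))
  }
  state$zeta[[j]][obs, ] <- ze
  state$phi[[j]] <- ph
  state$s1[j, ] <- g1
  state$s2[j, ] <- g2
  lstat <- matrix(0, K, state$V)
  lstat[, obs] <- t(ph) %*% t(ze * xo)           # K x obs counts
  list(state = state, lstat = lstat, nk = colSums(ph))
}

## expected per-sample mixture over global isoforms for sample j
psi_mix <- function(state, j) {
  w <- stick_ew(state$s1[j, ], state$s2[j, ])
  drop(w %*% state$phi[[j]])
}

plugin_loglik <- function(psi_bar, beta_bar, X) {
  probs <- psi_bar %*% beta_bar
  sum(t(X) * log(pmax(probs, 1e-300)))
}

## maximum-likelihood refinement of per-sample mixture proportions by EM,
## used to score catalog moves at comparable (optimised) likelihoods
em_psi <- function(psi, beta, X, iters = 150L, tol = 1e-7) {
  m <- nrow(psi)
  K <- ncol(psi)
  ## start from a mild flattening so EM can leave degenerate corners
  psi <- (psi + 0.05 / K) / (1 + 0.05)
  Xt <- t(X)
  tb <- t(beta)
  empty <- rowSums(Xt) == 0
  n <- pmax(rowSums(Xt), 1)
  last <- -Inf
  for (it in seq_len(iters)) {
    denom <- pmax(psi %*% beta, 1e-300)
    psi <- psi * ((Xt / denom) %*% tb) / n
    if (any(empty)) psi[empty, ] <- 1 / K
    if (it %% 5L == 0L) {
      ll <- sum(Xt * log(pmax(psi %*% beta, 1e-300)))
      if (ll - last < tol * (abs(ll) + 1)) break
      last <- ll
    }
  }
  list(psi = psi, ll = plugin_loglik(psi, beta, X))
}

## Penalised move objective: the optimised data log-likelihood minus a
## complexity term for the per-sample proportion parameters a K-isoform
## catalog introduces (0.5 * (K - 1) * sum_j log n_j, the Laplace/BIC
## surrogate for the DP prior mass an extra isoform must pay). Raw
## likelihood alone rewards fragmenting the catalog to fit per-sample
## multinomial noise at realistic read depths.
move_score <- function(ll, K, X) {
  ll - 0.5 * (K - 1) * sum(log(pmax(colSums(X), 2)))
}

svi_full_pass <- function(state, X, n_inner = 3L) {
  elogbeta <- log(state$beta_bar)
  elogw <- stick_elogw(state$ga, state$gb)
  K <- nrow(state$isoforms)
  lstat <- matrix(0, K, state$V)
  nk <- rep(0, K)
  for (j in seq_len(state$m)) {
    res <- svi_local(state, j, X[, j], elogbeta, elogw, n_inner)
    state <- res$state
    lstat <- lstat + res$lstat
    nk <- nk + res$nk
  }
  ## batch refresh of the global stick parameters at move boundaries
  state$ga <- 1 + nk
  state$gb <- state$hyp$omega + c(rev(cumsum(rev(nk)))[-1L], 0)
  state$psi_bar <- t(vapply(seq_len(state$m), function(j)
    psi_mix(state, j), numeric(K)))
  if (K == 1L) state$psi_bar <- matrix(1, state$m, 1L)
  state
}

## -- catalog moves ---------------------------------------------------------

#' Merge redundant isoforms
#'
#' For every pair of isoforms, computes the plug-in data likelihood
#' before and after reassigning both isoforms' mixture mass to a single
#' merged isoform (keeping whichever member's composition yields the
#' higher post-merge likelihood). Merges that do not decrease the
#' likelihood are accepted greedily, so duplicate compositions collapse
#' (ties prefer fewer isoforms).
#'
#' @param state An `svi_state` as produced during [fit()].
#' @param X V x m count matrix (or `read_term_matrix`).
#' @return The updated state.
#' @export
merge_step <- function(state, X) {
  if (inherits(X, "read_term_matrix")) X <- X$X
  repeat {
    K <- nrow(state$isoforms)
    if (K < 2L) return(state)
    pre <- move_score(em_psi(state$psi_bar, state$beta_bar, X)$ll, K, X)
    eta_v <- rep_len(state$hyp$eta, state$V)
    nt_cache <- new.env(parent = emptyenv())
    n_tot <- function(comp) {
      key <- as.character(encode_isoform(comp))
      if (is.null(nt_cache[[key]]))
        nt_cache[[key]] <- count_compatible_terms(state$gene, comp,
                                                  state$read_len)
      nt_cache[[key]]
    }
    best <- NULL
    for (k1 in seq_len(K - 1L)) for (k2 in (k1 + 1L):K) {
      psi_m <- state$psi_bar
      psi_m[, k1] <- psi_m[, k1] + psi_m[, k2]
      psi_m <- psi_m[, -k2, drop = FALSE]
      ## merged-composition candidates: either member, the exon
      ## intersection of the pair (the parsimonious common refinement of
      ## two inclusion closures), or the exon union (the assembly of two
      ## span-style fragments)
      cand <- list(state$isoforms[k1, ], state$isoforms[k2, ])
      comp_and <- state$isoforms[k1, ] * state$isoforms[k2, ]
      comp_or <- pmax(state$isoforms[k1, ], state$isoforms[k2, ])
      for (cc in list(comp_and, comp_or)) {
        if (any(cc == 1L) && !all(cc == cand[[1L]]) && !all(cc == cand[[2L]]))
          cand <- c(cand, list(cc))
      }
      for (comp in cand) {
        bi <- compat_matrix(matrix(comp, 1L), state$term_exons)
        beta_m <- state$beta_bar
        beta_m[k1, ] <- structural_emission(bi, eta_v, state$hyp$epsilon,
                                            n_tot(comp))
        beta_m <- beta_m[-k2, , drop = FALSE]
        ## cheap screening pass; the winner is re-scored to convergence
        ll <- move_score(em_psi(psi_m, beta_m, X, iters = 20L)$ll,
                         K - 1L, X)
        if (is.null(best) || ll > best$ll)
          best <- list(ll = ll, k1 = k1, k2 = k2, comp = comp,
                       psi_m = psi_m, beta_m = beta_m)
      }
    }
    if (!is.null(best))
      best$ll <- move_score(em_psi(best$psi_m, best$beta_m, X)$ll,
                            K - 1L, X)
    if (is.null(best) || best$ll < pre) return(state)
    ## apply the merge: merged composition lives in slot k1, k2 is dropped
    k1 <- best$k1; k2 <- best$k2
    merged_code <- encode_isoform(best$comp)
    state$tried <- union(state$tried,
                         setdiff(state$codes[c(k1, k2)], merged_code))
    state$isoforms[k1, ] <- best$comp
    state$codes[k1] <- merged_code
    sel <- setdiff(seq_len(K), k2)
    state$isoforms <- state$isoforms[sel, , drop = FALSE]
    state$codes <- state$codes[sel]
    state$b <- compat_matrix(state$isoforms, state$term_exons)
    eta <- rep_len(state$hyp$eta, state$V)
    state$prior <- state$b * rep(eta, each = K - 1L) +
      state$hyp$epsilon / state$V
    state$lambda <- state$prior
    state$n_total <- catalog_n_total(state)
    state$beta_bar <- structural_emission(state$b, eta,
                                          state$hyp$epsilon,
                                          state$n_total)
    for (j in seq_len(state$m)) {
      ph <- state$phi[[j]]
      ph[, k1] <- ph[, k1] + ph[, k2]
      state$phi[[j]] <- ph[, sel, drop = FALSE]
    }
    nk <- Reduce(`+`, lapply(state$phi, colSums))
    state$ga <- 1 + nk
    state$gb <- state$hyp$omega + c(rev(cumsum(rev(nk)))[-1L], 0)
    psi_m <- state$psi_bar
    psi_m[, k1] <- psi_m[, k1] + psi_m[, k2]
    state$psi_bar <- psi_m[, sel, drop = FALSE]
  }
}

#' Propose a novel isoform from poorly mapped reads
#'
#' Identifies read terms whose best posterior mapping probability to the
#' current isoforms is below the configured threshold (terms compatible
#' with no isoform at all always qualify), samples a random subset of
#' them, and proposes the isoform whose composition is the union of
#' their exons (exons skipped by every spanning sampled term are
#' excluded, exons outside the union are excluded). If the
#' proposal is novel, it is added to the catalog and all variational
#' parameters are reinitialised (the enlarged catalog is kept).
#' Compositions previously discarded by merge or reduce moves are not
#' re-proposed, which prevents propose/reduce oscillation.
#'
#' @inheritParams merge_step
#' @return The updated state, with attribute `proposed` (logical).
#' @export
propose_step <- function(state, X) {
  if (inherits(X, "read_term_matrix")) X <- X$X
  K <- nrow(state$isoforms)
  denom <- state$psi_bar %*% state$beta_bar          # m x V
  best <- matrix(0, state$m, state$V)
  for (k in seq_len(K))
    best <- pmax(best, outer(state$psi_bar[, k], state$beta_bar[k, ]))
  maxprob <- best / pmax(denom, 1e-300)
  ## a term incompatible with every isoform is only explained by the
  ## epsilon floor: poorly mapped regardless of its responsibility
  ## (responsibilities are vacuous at K = 1)
  orphan <- colSums(state$b) == 0L
  poorly <- which(t(X) > 0L &
                    (maxprob < state$cfg$poor_map_threshold |
                       rep(orphan, each = state$m)),
                  arr.ind = TRUE)
  attr(state, "proposed") <- FALSE
  if (nrow(poorly) == 0L) return(state)
  vs <- unique(poorly[, 2L])
  keep <- vs[stats::runif(length(vs)) < 0.5]
  if (length(keep) == 0L) keep <- vs[sample.int(length(vs), 1L)]
  comp <- union_composition(state$term_exons[keep], state$gene$E)
  code <- encode_isoform(comp)
  if (code %in% state$codes || code %in% state$tried ||
      K >= state$hyp$K_max)
    return(state)
  state$isoforms <- rbind(state$isoforms, matrix(comp, 1L))
  state$codes <- c(state$codes, code)
  state$tried <- union(state$tried, code)
  state <- svi_reinit(state)
  attr(state, "proposed") <- TRUE
  state
}

#' Remove unsupported isoforms
#'
#' Removes isoform k when no read in any sample has assignment
#' probability above the configured threshold (default 0.01) to k. The
#' final remaining isoform is never removed.
#'
#' @inheritParams merge_step
#' @return The updated state.
#' @export
reduce_step <- function(state, X) {
  if (inherits(X, "read_term_matrix")) X <- X$X
  K <- nrow(state$isoforms)
  if (K < 2L) return(state)
  supported <- rep(FALSE, K)
  usage <- rep(0, K)
  for (j in seq_len(state$m)) {
    obs <- which(X[, j] > 0L)
    if (length(obs) == 0L) next
    p <- state$zeta[[j]][obs, , drop = FALSE] %*% state$phi[[j]]  # obs x K
    supported <- supported | apply(p > state$cfg$reduce_threshold, 2L, any)
    usage <- usage + colSums(p * X[obs, j])
  }
  if (!any(supported)) supported[which.max(usage)] <- TRUE
  if (all(supported)) return(state)
  sel <- which(supported)
  state$tried <- union(state$tried, state$codes[!supported])
  state$isoforms <- state$isoforms[sel, , drop = FALSE]
  state$codes <- state$codes[sel]
  state$lambda <- state$lambda[sel, , drop = FALSE]
  state$b <- state$b[sel, , drop = FALSE]
  state$prior <- state$prior[sel, , drop = FALSE]
  for (j in seq_len(state$m)) {
    ph <- state$phi[[j]][, sel, drop = FALSE]
    state$phi[[j]] <- ph / pmax(rowSums(ph), 1e-12)
  }
  nk <- Reduce(`+`, lapply(state$phi, colSums))
  state$ga <- 1 + nk
  state$gb <- state$hyp$omega + c(rev(cumsum(rev(nk)))[-1L], 0)
  state$n_total <- state$n_total[sel]
  state$beta_bar <- state$beta_bar[sel, , drop = FALSE]
  state$psi_bar <- state$psi_bar[, sel, drop = FALSE]
  state$psi_bar <- state$psi_bar / pmax(rowSums(state$psi_bar), 1e-12)
  state
}

## plug-in MAP joint probability used to select among restarts
state_log_joint <- function(state, X) {
  psi <- state$psi_bar / rowSums(state$psi_bar)
  K <- nrow(state$isoforms)
  rtm_like <- X
  lj <- tryCatch(
    log_joint(structure(list(X = X, catalog = state$catalog),
                        class = "read_term_matrix"),
              global = list(isoforms = state$isoforms,
                            weights = stick_ew(state$ga, state$gb)),
              samples = list(psi = psi,
                             c = matrix(rep(seq_len(K), each = state$m),
                                        state$m)),
              hyp = state$hyp),
    error = function(e) -Inf)
  lj
}

#' Fit the isoform model by stochastic variational inference
#'
#' Runs SVI on a read-term count matrix: local (per-sample) coordinate
#' ascent on a random minibatch, then a noisy natural-gradient update of
#' the global stick-breaking and emission parameters with Robbins-Monro
#' step sizes. Every `move_period` iterations the catalog moves run in
#' order merge, propose, reduce. The fit terminates when the relative
#' change of the objective falls below `tol` (or at `max_iter`,
#' returning the last state flagged unconverged), and the restart with
#' the highest final joint probability is returned.
#'
#' @param rtm A `read_term_matrix` (all-zero matrices are rejected).
#' @param gene A [gene_model()].
#' @param hyp A [hyperparameters()].
#' @param cfg A [fit_config()].
#' @return An object of class `svi_fit`: `isoforms` (K x E), `codes`,
#'   `psi` (m x K per-sample proportions), `beta` (K x V emission
#'   means), `log_joint`, `loglik`, `trace` (iteration, objective, K),
#'   `converged`, plus the final `state`.
#' @export
fit <- function(rtm, gene, hyp = hyperparameters(), cfg = fit_config()) {
  stopifnot(inherits(rtm, "read_term_matrix"))
  X <- rtm$X
  if (sum(X) == 0L) stop("degenerate data: all read-term counts are zero")
  m <- ncol(X)
  best <- NULL
  for (r in seq_len(cfg$restarts)) {
    set.seed((cfg$seed + 7919L * (r - 1L)) %% .Machine$integer.max)
    state <- svi_init(rtm, gene, hyp, cfg)
    objs <- numeric(0)
    for (t in seq_len(cfg$max_iter)) {
      elogbeta <- log(state$beta_bar)
      elogw <- stick_elogw(state$ga, state$gb)
      mb <- sample.int(m, min(cfg$batch_size, m))
      K <- nrow(state$isoforms)
      lstat <- matrix(0, K, state$V)
      nk <- rep(0, K)
      for (j in mb) {
        res <- svi_local(state, j, X[, j], elogbeta, elogw, cfg$n_local)
        state <- res$state
        lstat <- lstat + res$lstat
        nk <- nk + res$nk
      }
      rho <- (t + cfg$delay)^(-cfg$forgetting)
      sc <- m / length(mb)
      state$ga <- (1 - rho) * state$ga + rho * (1 + sc * nk)
      state$gb <- (1 - rho) * state$gb +
        rho * (state$hyp$omega + sc * c(rev(cumsum(rev(nk)))[-1L], 0))
      for (j in mb) state$psi_bar[j, ] <- psi_mix(state, j)
      if (t %% cfg$move_period == 0L) {
        ## responsibilities are refreshed between moves: each step's
        ## decision rule reads read-level assignment probabilities
        state <- svi_full_pass(state, X)
        K_before <- nrow(state$isoforms)
        state <- merge_step(state, X)
        if (nrow(state$isoforms) != K_before)
          state <- svi_full_pass(state, X)
        state <- propose_step(state, X)
        if (isTRUE(attr(state, "proposed")))
          state <- svi_full_pass(state, X)
        state <- reduce_step(state, X)
        state <- svi_full_pass(state, X)
      }
      obj <- plugin_loglik(state$psi_bar, state$beta_bar, X)
      objs <- c(objs, obj)
      state$trace[[t]] <- c(iter = t, objective = obj,
                            K = nrow(state$isoforms))
      if (t > cfg$move_period + 5L) {
        recent <- utils::tail(objs, 5L)
        if (max(abs(diff(recent))) / (abs(obj) + 1e-8) < cfg$tol) {
          state$converged <- TRUE
          break
        }
      }
    }
    state <- svi_full_pass(state, X)
    lj <- state_log_joint(state, X)
    if (is.null(best) || lj > best$lj)
      best <- list(state = state, lj = lj, restart = r)
  }
  state <- best$state
  psi <- state$psi_bar / rowSums(state$psi_bar)
  colnames(psi) <- as.character(state$codes)
  rownames(psi) <- rtm$sample_ids
  trace <- as.data.frame(do.call(rbind, state$trace))
  structure(list(isoforms = state$isoforms, codes = state$codes,
                 psi = psi, beta = state$beta_bar,
                 log_joint = best$lj,
                 loglik = plugin_loglik(state$psi_bar, state$beta_bar, X),
                 trace = trace, converged = state$converged,
                 restart = best$restart, state = state, gene = state$gene,
                 sample_ids = rtm$sample_ids),
            class = "svi_fit")
}

#' @export
print.svi_fit <- function(x, ...) {
  cat(sprintf("svi_fit: %d isoform%s over %d samples (%sconverged, restart %d)\n",
              nrow(x$isoforms), if (nrow(x$isoforms) == 1L) "" else "s",
              nrow(x$psi), if (x$converged) "" else "not ", x$restart))
  cat("codes:", paste(x$codes, collapse = ", "), "\n")
  invisible(x)
}
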
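fit_quick <- function(sim, gene, seed = 1, restarts = 2) {
  fit(sim$rtm, gene, hyperparameters(),
      fit_config(seed = seed, restarts = restarts, max_iter = 120))
}

test_that("a single-isoform gene converges to K = 1 with that composition", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 0, 1)), m = 20,
                        reads_per_sample = 25, seed = 30)
  f <- fit_quick(sim, g)
  expect_equal(nrow(f$isoforms), 1L)
  expect_equal(f$codes, 5)
  expect_equal(unname(f$psi[, 1]), rep(1, 20))
})

test_that("identical seed and config reproduce identical traces", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1), c(1, 0, 1)), m = 15,
                        reads_per_sample = 20, seed = 31)
  f1 <- fit_quick(sim, g, seed = 5)
  f2 <- fit_quick(sim, g, seed = 5)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$psi, f2$psi)
  expect_identical(f1$codes, f2$codes)
})

test_that("degenerate all-zero data is rejected", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1)), m = 3,
                        reads_per_sample = 0, seed = 1)
  expect_error(fit(sim$rtm, g), "degenerate")
})

prepared_state <- function(sim, gene, passes = 6L) {
  cfg <- fit_config(seed = 3, restarts = 1)
  set.seed(cfg$seed)
  st <- spliceHDP:::svi_init(sim$rtm, gene, hyperparameters(), cfg)
  for (i in seq_len(passes)) st <- spliceHDP:::svi_full_pass(st, sim$rtm$X)
  st
}

test_that("merging never decreases the penalised data likelihood", {
  g <- fixture_gene(4L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1, 1), c(1, 0, 0, 1)), m = 30,
                        reads_per_sample = 25, seed = 33)
  st <- prepared_state(sim, g)
  X <- sim$rtm$X
  K0 <- nrow(st$isoforms)
  pre <- spliceHDP:::move_score(
    spliceHDP:::em_psi(st$psi_bar, st$beta_bar, X)$ll, K0, X)
  st2 <- merge_step(st, X)
  post <- spliceHDP:::move_score(
    spliceHDP:::em_psi(st2$psi_bar, st2$beta_bar, X)$ll,
    nrow(st2$isoforms), X)
  expect_gte(post, pre - 1e-6)
  expect_lte(nrow(st2$isoforms), K0)
})

test_that("duplicate compositions merge; K = 1 is a merge no-op", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1)), m = 10,
                        reads_per_sample = 20, seed = 35)
  st <- prepared_state(sim, g)
  X <- sim$rtm$X
  # plant an exact duplicate slot
  st$isoforms <- rbind(st$isoforms[1, ], st$isoforms[1, ])
  st$codes <- rep(st$codes[1], 2)
  st <- spliceHDP:::svi_reinit(st)
  st <- spliceHDP:::svi_full_pass(st, X)
  st2 <- merge_step(st, X)
  expect_equal(nrow(st2$isoforms), 1L)

  st3 <- merge_step(st2, X)   # K = 1: no-op
  expect_identical(st3$isoforms, st2$isoforms)
})

test_that("well-mapped data yields no proposal; incompatible terms do", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1)), m = 10,
                        reads_per_sample = 30, seed = 36)
  st <- prepared_state(sim, g)
  X <- sim$rtm$X
  st2 <- propose_step(st, X)
  expect_false(attr(st2, "proposed"))
  expect_equal(st2$codes, st$codes)

  # force a catalog that cannot explain the junction term {1,3}
  skip <- sample_dataset(g, rbind(c(1, 0, 1)), m = 10,
                         reads_per_sample = 30, seed = 37)
  cfg <- fit_config(seed = 3, restarts = 1)
  st3 <- spliceHDP:::svi_init(skip$rtm, g, hyperparameters(), cfg)
  st3$isoforms <- matrix(c(1L, 1L, 1L), 1L)
  st3$codes <- 7
  st3$tried <- numeric(0)
  st3 <- spliceHDP:::svi_reinit(st3)
  st3 <- spliceHDP:::svi_full_pass(st3, skip$rtm$X)
  set.seed(1)
  st4 <- propose_step(st3, skip$rtm$X)
  expect_true(attr(st4, "proposed"))
  expect_equal(nrow(st4$isoforms), 2L)
  # the proposal excludes the skipped middle exon
  expect_equal(st4$isoforms[2, 2], 0L)
})

test_that("reduce removes unsupported isoforms but never the last one", {
  g <- fixture_gene(3L)
  # data from (1,0,1): observed terms {1}, {3}, {1,3} only
  sim <- sample_dataset(g, rbind(c(1, 0, 1)), m = 10,
                        reads_per_sample = 25, seed = 38)
  X <- sim$rtm$X
  st <- prepared_state(sim, g)
  # plant an isoform incompatible with every observed term
  k1 <- which(st$codes == 5)[1]
  st$isoforms <- rbind(st$isoforms[k1, ], c(0L, 1L, 0L))
  st$codes <- c(5, 2)
  st <- spliceHDP:::svi_reinit(st)
  st <- spliceHDP:::svi_full_pass(st, X)
  st2 <- reduce_step(st, X)
  expect_equal(st2$codes, 5)
  # surviving isoforms all carry at least one read above threshold
  p_ok <- vapply(seq_len(st2$m), function(j) {
    obs <- which(X[, j] > 0)
    p <- st2$zeta[[j]][obs, , drop = FALSE] %*% st2$phi[[j]]
    max(p)
  }, numeric(1))
  expect_true(any(p_ok > 0.01))

  st3 <- reduce_step(st2, X)  # K = 1 guard
  expect_equal(nrow(st3$isoforms), 1L)
})

test_that("catalog size changes only at move boundaries", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1), c(1, 0, 1)), m = 20,
                        reads_per_sample = 20, seed = 39)
  f <- fit(sim$rtm, g, hyperparameters(),
           fit_config(seed = 2, restarts = 1, max_iter = 100,
                      move_period = 30))
  ks <- f$trace$K
  changes <- which(diff(ks) != 0)          # K recorded after iteration i+1
  expect_true(all((changes + 1) %% 30 == 0))
})
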
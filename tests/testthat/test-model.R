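test_that("hyperparameters validate", {
  expect_error(hyperparameters(omega = 0), "positive")
  expect_error(hyperparameters(K_max = 2, L_max = 5), "K_max >= L_max")
  h <- hyperparameters()
  expect_equal(h$alpha, 1)
  expect_equal(h$epsilon, 1e-3)
})

test_that("emission simplexes sum to 1 and floor every read term", {
  g <- fixture_gene(4L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1, 1), c(1, 0, 0, 1)),
                        m = 3, reads_per_sample = 40, seed = 2)
  te <- spliceHDP:::parse_exons(sim$rtm$catalog$exons)
  hyp <- hyperparameters()
  P <- spliceHDP:::emission_matrix(rbind(c(1, 1, 1, 1), c(1, 0, 0, 1)),
                                   te, hyp)
  expect_equal(rowSums(P), c(1, 1))
  V <- length(te)
  floor_mass <- (hyp$epsilon / V) / (sum(rep(1, V)) + hyp$epsilon)
  expect_true(all(P > 0))
  expect_true(all(P >= floor_mass * 0.5))
})

test_that("marginalised likelihood equals brute-force assignment enumeration", {
  g <- fixture_gene(3L)
  set.seed(21)
  for (trial in 1:12) {
    K <- sample(1:3, 1)
    isoforms <- matrix(0L, K, 3L)
    codes <- sample(1:7, K)
    for (k in seq_len(K)) isoforms[k, ] <- decode_isoform(codes[k], 3L)
    catalog <- data.frame(start = c(1L, 50L, 150L, 320L)[1:4],
                          end = c(40L, 120L, 380L, 390L)[1:4],
                          exons = c("1", "1", "1,2", "2"))
    V <- 4L
    n <- sample(1:6, 1)
    term_ids <- sample.int(V, n, replace = TRUE)
    X <- matrix(tabulate(term_ids, V), V, 1L)
    psi <- rdir <- stats::rgamma(K, 1)
    psi <- psi / sum(psi)
    hyp <- hyperparameters()
    rtm <- structure(list(X = X, catalog = catalog), class = "read_term_matrix")
    ll <- log_joint(rtm, global = list(isoforms = isoforms),
                    samples = list(psi = matrix(psi, 1L)),
                    hyp = hyp, include_prior = FALSE)
    P <- spliceHDP:::emission_matrix(isoforms,
                                     spliceHDP:::parse_exons(catalog$exons),
                                     hyp)
    expect_equal(ll, oracle_loglik_enum(term_ids, psi, P), tolerance = 1e-8)
  }
})

test_that("log joint is additive over i.i.d. sample columns", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1), c(1, 0, 1)),
                        m = 1, reads_per_sample = 25, seed = 4)
  X1 <- sim$rtm$X
  X2 <- cbind(X1, X1)
  rtm1 <- sim$rtm
  rtm2 <- structure(list(X = X2, catalog = sim$rtm$catalog),
                    class = "read_term_matrix")
  iso <- rbind(c(1, 1, 1), c(1, 0, 1))
  ll1 <- log_joint(rtm1, list(isoforms = iso),
                   list(psi = matrix(c(0.3, 0.7), 1L)),
                   include_prior = FALSE)
  ll2 <- log_joint(rtm2, list(isoforms = iso),
                   list(psi = matrix(c(0.3, 0.7), 2L, 2L, byrow = TRUE)),
                   include_prior = FALSE)
  expect_equal(ll2, 2 * ll1, tolerance = 1e-10)
  # prior-inclusive value is finite
  expect_true(is.finite(log_joint(rtm1, list(isoforms = iso),
                                  list(psi = matrix(c(0.3, 0.7), 1L)))))
  expect_error(log_joint(rtm1, list(isoforms = iso),
                         list(psi = matrix(c(0.5, 0.4), 1L))),
               "simplex")
})

test_that("the generative sampler is seeded and respects Dirichlet moments", {
  g <- fixture_gene(3L)
  iso <- rbind(c(1, 1, 1), c(1, 0, 1))
  a <- sample_dataset(g, iso, m = 5, reads_per_sample = 30, seed = 77)
  b <- sample_dataset(g, iso, m = 5, reads_per_sample = 30, seed = 77)
  expect_identical(a$rtm$X, b$rtm$X)
  expect_identical(a$truth$psi, b$truth$psi)

  # one isoform: every sample is a single simplex point
  one <- sample_dataset(g, rbind(c(1, 1, 1)), m = 4,
                        reads_per_sample = 10, seed = 5)
  expect_equal(one$truth$psi, matrix(1, 4, 1))

  # strong concentration at weights (0.7, 0.3): sample means within 3 SE
  hyp <- hyperparameters(alpha = 50)
  big <- sample_dataset(g, iso, hyp, m = 200, reads_per_sample = 1,
                        seed = 8, global_weights = c(0.7, 0.3))
  conc <- 50 * 2 * c(0.7, 0.3)
  v <- conc[1] * conc[2] / (sum(conc)^2 * (sum(conc) + 1))
  se <- sqrt(v / 200)
  expect_lt(abs(mean(big$truth$psi[, 1]) - 0.7), 3 * se)

  # zero reads: empty columns, no error
  z <- sample_dataset(g, iso, m = 3, reads_per_sample = 0, seed = 1)
  expect_equal(sum(z$rtm$X), 0L)
})
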
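test_that("transcript-ratio filters drop constant and rare transcripts", {
  n <- 100L
  ratios <- cbind(rep(0, n),                       # constant 0
                  rep(1, n),                       # constant 1
                  c(rep(0.5, 9), rep(0, n - 9)),   # expressed in 9%
                  runif(n, 0.2, 0.8),
                  runif(n, 0.2, 0.8))
  kept <- filter_transcripts(ratios)
  expect_equal(ncol(kept), 2L)

  # a 2-transcript gene with both variable transcripts is retained intact
  two <- cbind(runif(n, 0.1, 0.9), runif(n, 0.1, 0.9))
  expect_equal(ncol(filter_transcripts(two)), 2L)

  # genes left with a single transcript, or with < 3 exons, are dropped
  one <- cbind(rep(0, n), runif(n, 0.1, 0.9))
  expect_equal(ncol(filter_transcripts(one)), 0L)
  expect_equal(ncol(filter_transcripts(two, n_exons = 2L)), 0L)
})

test_that("Dirichlet MLE recovers parameters and respects symmetry", {
  set.seed(42)
  x <- t(vapply(1:5000, function(i) {
    g <- stats::rgamma(2, c(2, 5))
    g / sum(g)
  }, numeric(2)))
  a <- dirichlet_mle(x)
  expect_true(attr(a, "converged"))
  expect_lt(max(abs(a - c(2, 5)) / c(2, 5)), 0.1)

  # permutation-symmetric samples give symmetric estimates
  xs <- rbind(x[, c(1, 2)], x[, c(2, 1)])
  as <- dirichlet_mle(xs)
  expect_lt(abs(as[1] - as[2]), 1e-4)

  expect_error(dirichlet_mle(matrix(c(0.4, 0.6), 1)), ">= 2 samples")
  expect_error(dirichlet_mle(matrix(0.5, 4, 2)[, 1, drop = FALSE]),
               "dimension")
  expect_error(dirichlet_mle(matrix(rep(c(0.3, 0.7), each = 5), 5)),
               "degenerate")
})

test_that("Dirichlet MLE beats its method-of-moments start", {
  set.seed(9)
  for (i in 1:10) {
    d <- sample(2:4, 1)
    conc <- stats::runif(d, 0.5, 6)
    x <- t(vapply(1:200, function(j) {
      g <- stats::rgamma(d, conc)
      g / sum(g)
    }, numeric(d)))
    a <- dirichlet_mle(x)
    m1 <- colMeans(x)
    m2 <- mean(x[, 1]^2)
    s0 <- (m1[1] - m2) / max(m2 - m1[1]^2, 1e-12)
    mom <- pmax(m1 * max(s0, 1e-3), 1e-6)
    ll <- function(a) nrow(x) * (lgamma(sum(a)) - sum(lgamma(a))) +
      sum((a - 1) * colSums(log(x)))
    expect_gte(ll(a) + 1e-6, ll(mom))
  }
})

test_that("the group LR test is zero for identical groups and detects shifts", {
  set.seed(6)
  x <- t(vapply(1:80, function(i) {
    g <- stats::rgamma(3, c(3, 2, 1))
    g / sum(g)
  }, numeric(3)))
  same <- lr_test(rbind(x, x), rep(c("a", "b"), each = 80))
  expect_lt(same$statistic, 1e-4)
  expect_equal(same$df, 3L)

  xa <- t(vapply(1:100, function(i) {
    g <- stats::rgamma(2, c(8, 2)); g / sum(g) }, numeric(2)))
  xb <- t(vapply(1:100, function(i) {
    g <- stats::rgamma(2, c(2, 8)); g / sum(g) }, numeric(2)))
  strong <- lr_test(rbind(xa, xb), rep(c("a", "b"), each = 100))
  expect_lt(strong$p_value, 1e-6)

  expect_warning(
    lr_test(rbind(xa, xb[1, , drop = FALSE], xb[2:3, ]),
            c(rep("a", 100), "tiny", "b", "b")),
    "excluding")
  expect_error(lr_test(xa, rep("a", 100)), ">= 2 usable groups")
})

test_that("LR statistic is invariant to relabelling groups with their data", {
  set.seed(15)
  x <- t(vapply(1:60, function(i) {
    g <- stats::rgamma(2, c(2, 3)); g / sum(g) }, numeric(2)))
  grp <- rep(c("a", "b"), each = 30)
  s1 <- lr_test(x, grp)$statistic
  s2 <- lr_test(x, ifelse(grp == "a", "b", "a"))$statistic
  expect_equal(s1, s2, tolerance = 1e-10)
  expect_gte(s1, 0)
})

test_that("population-specific alleles follow the strict threshold rule", {
  v <- data.frame(allele = c("A", "A"), population = c("p1", "p2"),
                  count = c(9, 1))
  expect_true(population_specific(v, 0.8))     # 0.9 > 0.8
  eq <- data.frame(allele = c("A", "A"), population = c("p1", "p2"),
                   count = c(5, 5))
  expect_false(population_specific(eq, 0.5))   # 0.5 not > 0.5
  expect_true(population_specific(eq, 0))      # any expressed allele
  zero <- data.frame(allele = "A", population = c("p1", "p2"),
                     count = c(0, 0))
  expect_false(population_specific(zero, 0))   # zero-total allele skipped

  # monotone: raising t never flips FALSE -> TRUE
  set.seed(20)
  for (i in 1:20) {
    tab <- data.frame(allele = rep(c("A", "B"), each = 3),
                      population = rep(c("p1", "p2", "p3"), 2),
                      count = stats::rpois(6, 4))
    vals <- vapply(seq(0, 0.95, by = 0.05), function(t)
      population_specific(tab, t), logical(1))
    expect_true(all(diff(as.integer(vals)) <= 0))
  }
})

test_that("enrichment p-value matches the closed-form hypergeometric tail", {
  mk <- function(ids, spec) {
    do.call(rbind, lapply(seq_along(ids), function(i) {
      cnt <- if (spec[i]) c(9, 1) else c(5, 5)
      data.frame(variant = ids[i], allele = "A",
                 population = c("p1", "p2"), count = cnt, maf = 0.3)
    }))
  }
  # urn: N = 100, K = 10 specific, n = 20 drawn, k = 5 observed
  sel <- mk(paste0("s", 1:20), c(rep(TRUE, 5), rep(FALSE, 15)))
  bg <- mk(paste0("b", 1:80), c(rep(TRUE, 5), rep(FALSE, 75)))
  res <- enrichment_test(sel, bg, t = 0.8)
  manual <- sum(stats::dhyper(5:10, 10, 90, 20))
  expect_equal(res$p_value, manual, tolerance = 1e-12)
  expect_equal(res[c("k", "K", "n", "N")], list(k = 5L, K = 10L,
                                                n = 20L, N = 100L))

  # all specific alleles in the selected set: minimal attainable tail
  sel2 <- mk(paste0("s", 1:5), rep(TRUE, 5))
  bg2 <- mk(paste0("b", 1:45), rep(FALSE, 45))
  res2 <- enrichment_test(sel2, bg2, t = 0.8)
  expect_equal(res2$p_value, stats::dhyper(5, 5, 45, 5), tolerance = 1e-12)

  # identical composition: no enrichment
  sel3 <- mk(paste0("s", 1:20), rep(c(TRUE, FALSE), 10))
  bg3 <- mk(paste0("b", 1:20), rep(c(TRUE, FALSE), 10))
  expect_gte(enrichment_test(sel3, bg3, t = 0.8)$p_value, 0.5)

  expect_error(enrichment_test(sel, sel, t = 0.8), "disjoint")
  expect_error(enrichment_test(sel, bg[0, ], t = 0.8), "empty background")
})
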
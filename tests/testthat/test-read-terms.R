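test_that("the junction-spanning worked example reproduces exactly", {
  g <- fixture_brca2()
  tm <- read_to_term(40, 100, g)
  expect_equal(tm$start, 40L)
  expect_equal(tm$end, 2690L)
  expect_equal(tm$exons, 1:2)
  # 27 bases in exon 1 plus 73 in exon 2
  expect_equal((67 - 40) + (2690 - 2617), 100)
})

test_that("read terms walk exonic bases and reject invalid reads", {
  g <- fixture_brca2()
  tm <- read_to_term(2617, 50, g)
  expect_equal(tm, list(start = 2617L, end = 2667L, exons = 2L))
  expect_error(read_to_term(1000, 50, g), "unmappable")
  expect_error(read_to_term(2860, 50, g), "truncation")

  # 90 bp read across three 30 bp exons
  g3 <- gene_model("g3", c(1L, 101L, 201L), c(31L, 131L, 231L))
  tm3 <- read_to_term(1, 90, g3)
  expect_equal(tm3$exons, 1:3)
  expect_equal(tm3$end, 231L)
})

test_that("per-exon overlaps of any read term sum to the read length", {
  g <- fixture_gene(4L)
  set.seed(11)
  for (i in 1:200) {
    L <- sample(20:250, 1)
    gstart <- spliceHDP:::tx_to_genomic(
      g, sample.int(transcript_span(g) - L, 1) - 1L)
    tm <- read_to_term(gstart, L, g)
    ex <- g$exons[tm$exons, , drop = FALSE]
    overlaps <- pmin(ex$end, tm$end) - pmax(ex$start, tm$start)
    expect_equal(sum(overlaps), L)
  }
})

test_that("read term end is monotone in start within an exon", {
  g <- fixture_gene(3L)
  ends <- vapply(1:150, function(s) read_to_term(s, 120, g)$end, numeric(1))
  expect_true(all(diff(ends) >= 0))
})

test_that("count matrices union catalogs across samples", {
  t1 <- data.frame(start = c(1L, 50L), end = c(101L, 150L),
                   exons = c("1", "1"), count = c(3L, 4L))
  t2 <- data.frame(start = c(1L, 200L, 300L),
                   end = c(101L, 300L, 400L),
                   exons = c("1", "2", "2"), count = c(2L, 1L, 1L))
  rtm <- build_count_matrix(list(a = t1, b = t2))
  expect_equal(nrow(rtm$X), 4L)               # union of distinct terms
  expect_equal(colSums(rtm$X), c(a = 7L, b = 4L))
  expect_equal(sum(rtm$X == 0L), 3L)          # complementary zeros

  one <- build_count_matrix(list(s = data.frame(
    start = 1L, end = 101L, exons = "1", count = 7L)))
  expect_equal(unname(one$X), matrix(7L))

  attr(t1, "gene_id") <- "A"
  attr(t2, "gene_id") <- "B"
  expect_error(build_count_matrix(list(t1, t2)), "mixed-gene")
})

test_that("catalog reduction collapses similar starts and conserves counts", {
  # hand-collapse oracle: two terms, same exon set, starts 1 apart
  t1 <- data.frame(start = c(40L, 41L), end = c(140L, 141L),
                   exons = c("1", "1"), count = c(3L, 2L))
  rtm <- build_count_matrix(list(s = t1))
  red <- reduce_catalog(rtm, target = 1)
  expect_equal(nrow(red$X), 1L)
  expect_equal(sum(red$X), 5L)
  expect_equal(red$catalog$start, 40L)        # count-weighted mode

  # larger randomized fixture
  set.seed(5)
  n <- 400L
  tt <- data.frame(start = sample.int(2000L, n, replace = TRUE),
                   exons = sample(c("1", "2", "1,2", "1,3"), n, TRUE),
                   count = sample.int(5L, n, replace = TRUE))
  tt$end <- tt$start + 100L
  rtm2 <- build_count_matrix(list(s1 = tt[1:200, ], s2 = tt[201:400, ]))
  V0 <- nrow(rtm2$X)
  target <- 40L
  red2 <- reduce_catalog(rtm2, target)
  expect_lte(nrow(red2$X), V0)
  expect_gte(nrow(red2$X), 4L)                # never below distinct exon sets
  expect_equal(sum(red2$X), sum(rtm2$X))      # grand total conserved
  expect_equal(colSums(red2$X), colSums(rtm2$X))
  expect_lte(nrow(red2$X), 2L * target)
  # never merges different exon sets
  expect_setequal(unique(red2$catalog$exons), unique(rtm2$catalog$exons))

  # already under target: identity
  expect_identical(reduce_catalog(rtm, 100), rtm)
})

test_that("term TSV serialisation round-trips", {
  g <- fixture_gene(3L)
  sim <- sample_dataset(g, rbind(c(1, 1, 1), c(1, 0, 1)),
                        m = 4, reads_per_sample = 30, seed = 3)
  tf <- tempfile(fileext = ".tsv")
  write_term_matrix(sim$rtm, tf)
  back <- read_term_matrix_tsv(tf)
  expect_equal(back$X, sim$rtm$X)
  expect_equal(back$catalog$start, sim$rtm$catalog$start)
  expect_equal(back$catalog$exons, sim$rtm$catalog$exons)
})

test_that("aligned reads in SAM convert to the same read terms", {
  g <- fixture_gene(3L)
  sim <- simulate_gene_reads(sim_config(gene = g, isoforms = rbind(c(1, 1, 1)),
                                        m = 1, coverage = 3, seed = 9))
  sam <- tempfile(fileext = ".sam")
  write_sam(sim$reads, g, sam)
  terms <- terms_from_alignments(sam, g)
  expect_equal(attr(terms, "n_dropped"), 0L)
  expect_equal(sum(terms$count), nrow(sim$reads))
  got <- terms[order(terms$start, terms$end), ]
  want <- stats::aggregate(list(count = rep(1L, nrow(sim$reads))),
                           by = sim$reads[c("start", "end", "exons")],
                           FUN = sum)
  want <- want[order(want$start, want$end), ]
  expect_equal(got$start, want$start)
  expect_equal(got$end, want$end)
  expect_equal(got$exons, want$exons)
  expect_equal(got$count, want$count)
})
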
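test_that("independence table gives OR 1 and p 1", {
  A <- c(sprintf("x%02d", 1:10), sprintf("s%02d", 1:10))
  B <- c(sprintf("y%02d", 1:10), sprintf("s%02d", 1:10))
  univ <- c(A, sprintf("y%02d", 1:10), sprintf("z%02d", 1:10))
  r <- fisher_overlap(A, B, univ)
  expect_equal(unname(r$table), c(10, 10, 10, 10))
  expect_equal(r$odds_ratio, 1)
  expect_equal(r$p_value, 1)
})

test_that("headline-scale overlap is beyond the 2.2e-16 reporting floor", {
  risk <- read_gene_set(system.file("extdata", "synthetic_risk_genes.txt",
                                    package = "netoverlap"))
  targets <- read_gene_set(system.file("extdata", "synthetic_drug_targets.txt",
                                       package = "netoverlap"))
  r <- fisher_overlap(risk, targets, universe = 20000)
  expect_equal(length(r$overlap_genes), 17)
  expect_lte(r$p_value, 2.2e-16)
  expect_gt(r$odds_ratio, 1)
})

test_that("two-sided Fisher p matches exhaustive enumeration for all small tables", {
  for (m1 in 1:12) for (m2 in 1:12) {
    n <- 16
    lo <- max(0, m1 + m2 - n)
    for (a in lo:min(m1, m2)) {
      b <- m1 - a; cc <- m2 - a; d <- n - a - b - cc
      A <- sprintf("g%03d", seq_len(m2))
      B <- c(A[seq_len(a)], sprintf("h%03d", seq_len(b)))
      univ <- sprintf("g%03d", seq_len(n))
      univ <- unique(c(A, B, univ))[seq_len(n)]
      r <- fisher_overlap(A, B, univ)
      expect_equal(r$p_value, bf_fisher_two_sided(a, b, cc, d),
                   tolerance = 1e-9,
                   label = sprintf("a=%d b=%d c=%d d=%d", a, b, cc, d))
    }
  }
})

test_that("fisher p is invariant to swapping the two sets", {
  A <- sprintf("a%02d", 1:8); B <- c("a01", "a02", sprintf("b%02d", 1:5))
  univ <- unique(c(A, B, sprintf("u%02d", 1:30)))
  expect_equal(fisher_overlap(A, B, univ)$p_value,
               fisher_overlap(B, A, univ)$p_value)
})

test_that("genes outside the universe are dropped with a warning", {
  expect_warning(r <- fisher_overlap(c("a", "b", "q"), c("b", "c"),
                                     c("a", "b", "c", "d")),
                 "not in the universe")
  expect_equal(unname(r$table["a"]), 1)
})

test_that("Bonferroni and BH behave per definition", {
  expect_equal(adjust_pvalues(c(0.01, 0.02, 0.03), "bonferroni"),
               c(0.03, 0.06, 0.09))
  expect_equal(adjust_pvalues(0.5, "bh"), 0.5)
  expect_error(adjust_pvalues(c(0.1, 1.2), "bh"), "0, 1")
  set.seed(90)
  for (i in 1:25) {
    p <- runif(sample(1:8, 1))
    bh <- adjust_pvalues(p, "bh")
    bonf <- adjust_pvalues(p, "bonferroni")
    expect_equal(bh, bf_bh(p), tolerance = 1e-12)
    expect_true(all(bh <= bonf + 1e-12))
    expect_true(all(bh >= p - 1e-12))
    expect_true(all(bonf >= p - 1e-12))
  }
})

test_that("hypergeometric pmf over the support sums to one and the tail is monotone", {
  N <- 60; K <- 12; nq <- 15
  probs <- vapply(max(0, K + nq - N):min(K, nq), function(x)
    exp(lchoose(K, x) + lchoose(N - K, nq - x) - lchoose(N, nq)), numeric(1))
  expect_equal(sum(probs), 1, tolerance = 1e-12)
  tails <- phyper(0:min(K, nq) - 1, K, N - K, nq, lower.tail = FALSE)
  expect_true(all(diff(tails) <= 1e-12))
})

test_that("a query equal to one GMT set ranks it first with the minimal p", {
  univ <- sprintf("u%04d", 1:1000)
  sets <- list(target = univ[1:20],
               other1 = univ[101:140], other2 = univ[201:260])
  res <- gmt_enrichment(univ[1:20], sets, univ)
  expect_equal(res$set_name[1], "target")
  expect_equal(res$p_value[1], 1 / choose(1000, 20) * 1, tolerance = 1e-6)
})

test_that("overlap at the null expectation is not significant", {
  univ <- sprintf("u%04d", 1:2000)
  set.seed(91)
  sets <- list(s = sample(univ, 100))
  query <- c(sample(sets$s, 5), sample(setdiff(univ, sets$s), 95))  # E = 5
  res <- gmt_enrichment(query, sets, univ)
  expect_gt(res$p_value[1], 0.05)
  expect_gt(res$fdr[1], 0.05)
})

test_that("a planted GMT set is recovered at FDR < 0.01", {
  univ <- sprintf("u%04d", 1:2000)
  set.seed(92); query <- sample(univ, 50)
  sets <- simulate_gmt(query, univ, n_sets = 50, set_size = 40,
                       planted_frac = 0.8, seed = 93)
  res <- gmt_enrichment(query, sets, univ)
  expect_equal(res$set_name[1], "planted_set")
  expect_lt(res$fdr[1], 0.01)
})

test_that("sets with no universe genes are skipped with a warning", {
  univ <- c("a", "b", "c", "d")
  expect_warning(res <- gmt_enrichment(c("a", "b"),
                                       list(ok = c("a", "c"), gone = c("x", "y")),
                                       univ),
                 "skipped")
  expect_equal(nrow(res), 1)
})
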
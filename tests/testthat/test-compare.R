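test_that("column_score is the Pearson correlation with a uniform guard", {
  expect_equal(column_score(c(1, 0, 0, 0), c(1, 0, 0, 0)), 1)
  # derived by direct evaluation of the Pearson formula on 4-vectors
  expect_equal(column_score(c(1, 0, 0, 0), c(0, 1, 0, 0)), -1 / 3)
  expect_equal(column_score(rep(0.25, 4), c(1, 0, 0, 0)), 0)
  expect_equal(column_score(c(0.7, 0.1, 0.1, 0.1), rep(0.25, 4)), 0)
  expect_error(column_score(c(-0.1, 0.4, 0.4, 0.3), rep(0.25, 4)),
               "negative")
})

test_that("reverse_complement reverses columns and swaps complements", {
  a_col <- matrix(c(1, 0, 0, 0), 4, 1)
  expect_equal(unname(reverse_complement(a_col)),
               matrix(c(0, 0, 0, 1), 4, 1))
  m <- peak_motif("m", "ACGGTA")
  expect_equal(reverse_complement(reverse_complement(m))$mat, m$mat)
  # palindrome maps to itself
  p <- peak_motif("p", "ACGT")
  expect_equal(reverse_complement(p)$mat, p$mat)
})

test_that("best_alignment finds self-alignment and counts offsets", {
  cfg <- compare_config()
  m <- peak_motif("m", "ACGTTGCA")
  al <- best_alignment(m, m, cfg)
  expect_equal(al$offset, 0L)
  expect_equal(al$orientation, "+")
  expect_equal(al$raw, 8, tolerance = 1e-9)  # each aligned column scores 1
  # strand symmetry: query vs its reverse complement
  al2 <- best_alignment(m, reverse_complement(m), cfg)
  expect_equal(al2$raw, al$raw, tolerance = 1e-9)
  expect_equal(al2$orientation, "-")
  # offset enumeration: two L = 6 motifs, min_overlap 4, both strands
  a <- peak_motif("a", "ACGTAC"); b <- peak_motif("b", "GTTGCA")
  expect_equal(best_alignment(a, b, cfg)$n_offsets, 10L)
  expect_equal(best_alignment(a, b, compare_config(strands = "forward"))$n_offsets,
               5L)
  expect_error(best_alignment(peak_motif("s", "ACG"), m, cfg), "too short")
})

test_that("permutation p-values follow the (1+k)/(1+N) estimator", {
  set.seed(11)
  pool <- random_pool(60)
  # observed raw below essentially every decoy: uniform target scores 0
  q <- peak_motif("q", "ACGTACGT")
  unif <- motif("u", matrix(0.25, 4, 8), is_counts = FALSE)
  ps <- motif_pvalue(q, unif, pool, compare_config(seed = 5))
  expect_equal(ps$p_value, 1)
  expect_equal(ps$score, 0)

  # observed beats all 999 decoys: p = 1/1000, score exactly 3
  weak <- matrix(rep(c(0.4, 0.2, 0.2, 0.2), 40), 4)  # uninformative pool
  ps2 <- motif_pvalue(q, q, weak, compare_config(n_null = 999, seed = 5))
  expect_equal(ps2$p_value, 1 / 1000)
  expect_equal(ps2$score, 3)
  expect_error(motif_pvalue(q, q, matrix(numeric(0), 4, 0),
                            compare_config()), "empty")
})

test_that("motif_score is symmetric and deterministic under the seed", {
  set.seed(3)
  pool <- random_pool(50)
  a <- peak_motif("a", "ACGTACGTAA")
  b <- peak_motif("b", "CCGTACG")
  for (mode in c("permutation", "dp_exact")) {
    cfg <- compare_config(null_mode = mode, seed = 9)
    s1 <- motif_score(a, b, pool, cfg)
    s2 <- motif_score(b, a, pool, cfg)
    expect_equal(s1$score, s2$score)
    expect_equal(s1$score, motif_score(a, b, pool, cfg)$score)
  }
})

test_that("dp_exact on a 1-column query matches enumeration over the pool", {
  cfg <- compare_config(null_mode = "dp_exact", min_overlap = 1,
                        strands = "forward", n_bins = 100)
  q <- motif("q", matrix(c(0.9, 0.04, 0.03, 0.03), 4, 1), is_counts = FALSE)
  t <- motif("t", matrix(c(0.8, 0.1, 0.05, 0.05), 4, 1), is_counts = FALSE)
  pool <- cbind(c(0.8, 0.1, 0.05, 0.05), c(0.1, 0.1, 0.1, 0.7))
  ps <- motif_pvalue(q, t, pool, cfg)
  # enumeration over the 2 equiprobable pool columns with the same binning
  bin <- function(s) pmin(99, pmax(0, floor((s + 1) / 2 * 100)))
  obs <- bin(column_score(q$mat[, 1], t$mat[, 1]))
  null_bins <- bin(c(column_score(q$mat[, 1], pool[, 1]),
                     column_score(q$mat[, 1], pool[, 2])))
  expect_equal(ps$p_value, mean(null_bins >= obs))
})

test_that("score_pairs is invariant to evaluation order and cacheable", {
  g <- generate_planted_collection(synth_config(
    n_classes = 1, families_per_class = 2, subfamilies_per_family = 1,
    tfs_per_subfamily = 2, seed = 31))
  cfg <- compare_config(seed = 4, n_null = 200)
  ids <- names(g$collection$motifs)
  prs <- t(combn(ids, 2))
  s1 <- score_pairs(g$collection, cfg, prs)
  s2 <- score_pairs(g$collection, cfg, prs[rev(seq_len(nrow(prs))), ])
  for (k in seq_len(nrow(prs)))
    expect_equal(get_score(s1, prs[k, 1], prs[k, 2]),
                 get_score(s2, prs[k, 1], prs[k, 2]))
  expect_error(get_score(s1, "nope", ids[1]), "no score")
})

test_that("scores degrade monotonically with Dirichlet column noise", {
  # copies of a motif at decreasing concentration (more noise) score a
  # non-increasing median under the exact null
  set.seed(77)
  pool <- random_pool(80)
  base <- random_pool(10, alpha = 0.3)
  cfg <- compare_config(null_mode = "dp_exact")
  meds <- vapply(c(64, 8, 1), function(kappa) {
    sc <- vapply(1:20, function(i) {
      noisy <- vapply(seq_len(ncol(base)), function(j) {
        x <- rgamma(4, kappa * base[, j] + 1e-9)
        x / sum(x)
      }, numeric(4))
      motif_score(motif("o", base, is_counts = FALSE),
                  motif("n", noisy, is_counts = FALSE), pool, cfg)$score
    }, 0)
    median(sc)
  }, 0)
  expect_true(all(diff(meds) <= 0))
  expect_lt(meds[3], meds[1])
})
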
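test_that("tf_pair_score aggregates the N_X x N_Y motif-pair scores", {
  X <- tf_record("X", "1.1.1.1", c("x1", "x2"))
  Y <- tf_record("Y", "1.1.2.1", c("y1", "y2", "y3"))
  sc <- fake_scores(a = rep(c("x1", "x2"), each = 3),
                    b = rep(c("y1", "y2", "y3"), 2),
                    score = c(1.2, 4.0, 0.5, 2.0, 3.0, 1.0))
  expect_equal(tf_pair_score(X, Y, sc, metric_config("max")), 4.0)
  expect_equal(tf_pair_score(X, Y, sc,
                             metric_config(tf_pair_aggregator = "min")),
               0.5)
  expect_equal(tf_pair_score(X, Y, sc,
                             metric_config(tf_pair_aggregator = "median")),
               median(c(1.2, 4, 0.5, 2, 3, 1)))
  # single-motif TFs reduce to the single motif score
  A <- tf_record("A", "1.1.1.1", "a1"); B <- tf_record("B", "1.1.1.2", "b1")
  sc1 <- fake_scores("a1", "b1", 2.5)
  expect_equal(tf_pair_score(A, B, sc1), 2.5)
  # a missing motif pair is an error, not a silent NA
  expect_error(tf_pair_score(X, tf_record("Z", "1.1.3.1", "z9"), sc),
               "no score")
})

test_that("tf_heterogeneity is the median over intra-TF motif pairs", {
  single <- tf_record("S", "1.1.1.1", "s1")
  expect_true(is.na(tf_heterogeneity(single, fake_scores("a", "b", 1))))
  two <- tf_record("D", "1.1.1.1", c("d1", "d2"))
  expect_equal(tf_heterogeneity(two, fake_scores("d1", "d2", 6.3)), 6.3)
  # 4 motifs, 6 pairs, half below threshold: the median decides the flag
  four <- tf_record("Q", "1.1.1.1", paste0("q", 1:4))
  prs <- combn(paste0("q", 1:4), 2)
  vals <- c(1, 2, 2.5, 5, 6, 7)
  sc <- fake_scores(prs[1, ], prs[2, ], vals)
  expect_equal(tf_heterogeneity(four, sc), median(vals))
})

test_that("set_similarity builds the right pair distribution", {
  cfg <- metric_config()
  # intra-set of 2 single-motif TFs: all five metrics equal the pair score
  A <- fake_tf("A"); B <- fake_tf("B", "1.1.1.2")
  s <- set_similarity(list(A, B), NULL, fake_scores("A", "B", 2.2), cfg)
  expect_equal(unlist(s[c("min", "q1", "q2", "q3", "max")]),
               rep(2.2, 5), ignore_attr = TRUE)
  expect_equal(s$n_pairs, 1L)
  expect_equal(s$kind, "intra")

  # five single-motif TFs with pair values 0..4 by construction
  tfs <- lapply(1:5, function(i) fake_tf(paste0("T", i),
                                         paste0("1.1.1.", i)))
  prs <- combn(paste0("T", 1:5), 2)
  # give one chosen pair per target value, remaining pairs fill in
  vals <- c(0, 1, 2, 3, 4, 2, 2, 2, 2, 2)
  sc <- fake_scores(prs[1, ], prs[2, ], vals)
  s5 <- set_similarity(tfs, NULL, sc, cfg)
  expect_equal(s5$n_pairs, 10L)
  expect_equal(s5$min, 0); expect_equal(s5$max, 4)
  expect_equal(s5$q2, 2)

  # linear interpolation on an even-length distribution {1,2,3,4}
  t4 <- lapply(1:4, function(i) fake_tf(paste0("U", i), "2.1.1.1"))
  p4 <- combn(paste0("U", 1:4), 2)
  sc4 <- fake_scores(p4[1, ], p4[2, ], c(1, 2, 3, 4, 2.5, 2.5))
  # inter-set route gives exactly {1,2,3,4}: 2 x 2 TFs
  sI <- set_similarity(t4[1:2], t4[3:4],
                       fake_scores(c("U1", "U1", "U2", "U2"),
                                   c("U3", "U4", "U3", "U4"),
                                   c(1, 2, 3, 4)), cfg)
  expect_equal(sI$q2, 2.5)
  expect_equal(sI$n_pairs, 4L)
  expect_equal(sI$kind, "inter")
})

test_that("degenerate intra-set cases fall back as documented", {
  # one TF with several motifs: quartiles of its own motif-pair scores
  multi <- tf_record("M", "1.1.1.1", c("m1", "m2"))
  s <- set_similarity(list(multi), NULL, fake_scores("m1", "m2", 6.32))
  expect_equal(s$q2, 6.32)
  expect_equal(s$n_pairs, 1L)
  # one TF with one motif: no distribution at all (brown-circle case)
  s0 <- set_similarity(list(fake_tf("S")), NULL, fake_scores("a", "b", 1))
  expect_true(all(is.na(unlist(s0[c("min", "q1", "q2", "q3", "max")]))))
  expect_equal(s0$n_pairs, 0L)
  expect_error(set_similarity(list(), NULL, fake_scores("a", "b", 1)),
               "empty")
})

test_that("set_similarity is permutation-invariant and ordered", {
  set.seed(21)
  tfs <- lapply(1:6, function(i) fake_tf(paste0("P", i), "3.1.1.1"))
  prs <- combn(paste0("P", 1:6), 2)
  sc <- fake_scores(prs[1, ], prs[2, ], round(runif(15, 0, 8), 3))
  s1 <- set_similarity(tfs, NULL, sc)
  s2 <- set_similarity(rev(tfs), NULL, sc)
  expect_equal(unclass(s1), unclass(s2))
  expect_true(s1$min <= s1$q1 && s1$q1 <= s1$q2 &&
              s1$q2 <= s1$q3 && s1$q3 <= s1$max)
})

test_that("similarity_matrix is symmetric with NA brown-circle diagonal", {
  u <- list(
    fam1 = list(fake_tf("A", "1.1.1.1"), fake_tf("B", "1.1.1.2")),
    fam2 = list(fake_tf("C", "1.1.2.1")))   # one TF, one motif
  prs <- rbind(c("A", "B", 5), c("A", "C", 1), c("B", "C", 2))
  sc <- fake_scores(prs[, 1], prs[, 2], as.numeric(prs[, 3]))
  sm <- similarity_matrix(u, sc)
  expect_equal(sm$q2, t(sm$q2))
  expect_equal(sm$q2["fam1", "fam1"], 5)
  expect_true(is.na(sm$q2["fam2", "fam2"]))
  expect_equal(sm$q2["fam1", "fam2"], 1.5)
  expect_equal(sm$n_pairs["fam1", "fam2"], 2)
  # overlapping units are rejected
  expect_error(similarity_matrix(list(a = u$fam1, b = u$fam1), sc),
               "overlap")
})

test_that("is_similar is strict at the threshold", {
  expect_false(is_similar(3.0))
  expect_true(is_similar(3.0 + 1e-6))
  expect_false(is_similar(NA_real_))
})
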
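# fabricated 3-family class: fam A = {A1,A2}, fam B = {B1,B2}, fam C = {C1}
three_family_setup <- function(ab = 5, ac = 1, bc = 1,
                               intra_a = 6, intra_b = 6) {
  recs <- list(
    A1 = fake_tf("A1", "1.1.1.1"), A2 = fake_tf("A2", "1.1.1.2"),
    B1 = fake_tf("B1", "1.1.2.1"), B2 = fake_tf("B2", "1.1.2.2"),
    C1 = fake_tf("C1", "1.1.3.1"))
  val <- function(x, y) {
    fx <- substr(x, 1, 1); fy <- substr(y, 1, 1)
    if (fx == fy) return(if (fx == "A") intra_a else intra_b)
    key <- paste(sort(c(fx, fy)), collapse = "")
    switch(key, AB = ab, AC = ac, BC = bc)
  }
  prs <- combn(names(recs), 2)
  sc <- fake_scores(prs[1, ], prs[2, ],
                    mapply(val, prs[1, ], prs[2, ]))
  list(recs = recs, scores = sc)
}

test_that("agglomerate recomputes Q2 on the full merged distribution", {
  st <- three_family_setup(ab = 5, ac = 1, bc = 1)
  units <- list(`1.1.1` = st$recs[c("A1", "A2")],
                `1.1.2` = st$recs[c("B1", "B2")],
                `1.1.3` = st$recs["C1"])
  tr <- agglomerate(units, st$scores)
  # first join is (A, B) at their inter Q2 = 5
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))
  expect_equal(tr$height[1], 5)
  # second join: Q2 over the |A u B| x |C| = 4 pairs {1,1,1,1} = 1
  expect_equal(tr$height[2], 1)
  # two units: a single join at their inter Q2
  tr2 <- agglomerate(units[1:2], st$scores)
  expect_equal(nrow(tr2$merge), 1L)
  expect_equal(tr2$height, 5)
})

test_that("duplicate-like units join first at the maximal Q2", {
  recs <- list(D1 = fake_tf("D1", "2.1.1.1"), D2 = fake_tf("D2", "2.1.2.1"),
               E1 = fake_tf("E1", "2.1.3.1"))
  prs <- combn(names(recs), 2)
  sc <- fake_scores(prs[1, ], prs[2, ], c(9, 0.5, 0.5))  # D1-D2 identical-ish
  tr <- agglomerate(list(u1 = recs["D1"], u2 = recs["D2"],
                         u3 = recs["E1"]), sc)
  expect_equal(sort(tr$merge[1, ]), c(-2L, -1L))
  expect_equal(max(tr$height), tr$height[1])
})

test_that("find_branches handles whole-class, merged and singleton cases", {
  # class with overall high similarity collapses to one class branch
  st_hi <- three_family_setup(ab = 6, ac = 6, bc = 6)
  br <- find_branches(st_hi$recs, st_hi$scores)
  expect_equal(nrow(br), 1L)
  expect_equal(br$level, "class")
  expect_equal(br$n_tfs, 5L)

  # A+B merge, C recurses down to a singleton TF branch; the intra
  # values keep the class-wide median below the threshold
  st <- three_family_setup(ab = 5, ac = 1, bc = 1,
                           intra_a = 2, intra_b = 2)
  br2 <- find_branches(st$recs, st$scores)
  expect_setequal(br2$level, c("family", "tf"))
  merged <- br2[br2$level == "family", ]
  expect_equal(merged$members, "1.1.1;1.1.2")
  expect_equal(merged$n_tfs, 4L)
  ml <- merge_log(br2)
  expect_equal(nrow(ml), 1L)
  expect_equal(ml$value, 5)

  # all pairs scoring 0: one singleton branch per TF
  prs <- combn(names(st$recs), 2)
  sc0 <- fake_scores(prs[1, ], prs[2, ], rep(0, ncol(prs)))
  br0 <- find_branches(st$recs, sc0)
  expect_equal(nrow(br0), 5L)
  expect_true(all(br0$level == "tf"))
})

test_that("internally similar lone families become family branches", {
  st <- three_family_setup(ab = 1, ac = 1, bc = 1,
                           intra_a = 8, intra_b = 0.5)
  br <- find_branches(st$recs, st$scores)
  # family A stands alone as a branch; B's TFs and C1 end as singletons
  a_row <- br[br$members == "1.1.1", ]
  expect_equal(a_row$level, "family")
  expect_equal(a_row$internal_q2, 8)
  expect_equal(sum(br$level == "tf"), 3L)
  # partition covers every TF exactly once
  expect_setequal(names(branch_assignment(br)), names(st$recs))
})

test_that("branches never span classes", {
  recs <- list(X1 = fake_tf("X1", "1.1.1.1"), X2 = fake_tf("X2", "1.2.1.1"))
  sc <- fake_scores("X1", "X2", 9)  # huge cross-class similarity
  br <- find_branches(recs, sc)
  expect_equal(nrow(br), 2L)
  expect_true(all(br$n_tfs == 1L))
})

test_that("flag_heterogeneous_tfs flags multi-motif TFs under threshold", {
  recs <- list(
    tf_record("GOOD", "1.1.1.1", c("g1", "g2")),
    tf_record("BAD", "1.1.1.2", c("b1", "b2")),
    tf_record("LONE", "1.1.1.3", "l1"))
  sc <- fake_scores(c("g1", "b1"), c("g2", "b2"), c(8, 1.2))
  fl <- flag_heterogeneous_tfs(recs, sc)
  expect_equal(fl$tf_name, "BAD")
  expect_equal(fl$heterogeneity, 1.2)
})

test_that("export_newick emits parseable trees with clamped reversals", {
  st <- three_family_setup(ab = 5, ac = 1, bc = 1,
                           intra_a = 3.99, intra_b = 6)
  units <- list(`1.1.1` = st$recs[c("A1", "A2")],
                `1.1.2` = st$recs[c("B1", "B2")],
                `1.1.3` = st$recs["C1"])
  tr <- agglomerate(units, st$scores)
  nwk <- export_newick(tr)
  expect_match(nwk, ";$")
  # family 1.1.1 has internal Q2 3.99 below its merge value 5: reversal
  expect_true("1.1.1" %in% attr(nwk, "reversals"))
  expect_match(nwk, "1.1.1:0\\b")
  skip_if_not_installed("ape")
  tree <- ape::read.tree(text = as.character(nwk))
  expect_setequal(tree$tip.label, c("1.1.1", "1.1.2", "1.1.3"))
  expect_true(all(tree$edge.length >= 0))
})

test_that("TFs lacking deep annotation form pseudo-units", {
  recs <- list(fake_tf("P1", "1.1"), fake_tf("P2", "1.1.1"))
  sc <- fake_scores("P1", "P2", 0.5)
  br <- find_branches(recs, sc)
  expect_equal(nrow(br), 2L)
  expect_error(find_branches(list(fake_tf("S1", "1")), sc),
               "class level")
})
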
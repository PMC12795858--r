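# tfbranch

Transcription factors (TFs) are classified by the structure of their
DNA-binding domain (DBD) into a hierarchy of superclasses, classes,
families and subfamilies (dotted numerals, e.g. the Jun subfamily
`{1.1.1.1}`). Binding-site motifs — 4×L nucleotide frequency matrices
from ChIP-seq/HT-SELEX collections such as Hocomoco or JASPAR — follow
this hierarchy only loosely: some families share essentially one motif,
others are heterogeneous, and a single TF can carry several dissimilar
motif variants. `tfbranch` quantifies that relationship and partitions
the hierarchy into **branches**: maximal sets of sister units whose TFs
have significantly similar binding-site motifs. Branches are useful for
interpreting de novo motif enrichment: a motif matched to any member of
a branch implicates the whole branch, not a single arbitrary TF.

## The method

1. **Motif-pair score.** Two motifs `M_i`, `M_j` are compared
   TomTom-style: every gapless offset on both strands (overlap ≥ 4
   columns by default) is scored by the sum of per-column Pearson
   correlations of the frequency 4-vectors, and the best alignment is
   assigned a p-value against a null of targets assembled from the
   collection's column pool. `Score(M_i, M_j) = −log10 p`; a pair is
   significantly similar when `Score > Thr = 3` (strict). Two null
   models are provided: a seeded permutation null (`(1+k)/(1+N)`
   estimator, scores capped at `log10(N+1)`) and an exact discretized
   convolution null (`dp_exact`) for database-scale scores.
2. **TF-pair score.** TFs X and Y with `N_X`/`N_Y` motifs are compared
   through the distribution of all `N_X × N_Y` motif-pair scores
   (default aggregator: max). A single TF's motif **heterogeneity** is
   the median over its own `N(N−1)/2` motif pairs.
3. **Set metrics.** Two TF sets (families, subfamilies, …) with K and T
   TFs are compared through the `K(K−1)/2` (intra) or `K·T` (inter)
   TF-pair score distribution, summarized by Min, Q1, **Q2 (median)**,
   Q3 and Max; Q2 > Thr means more than half of all TF pairs are
   significantly similar.
4. **Branches.** Within each class, sister units are merged greedily:
   while any pair of current clusters has inter-set Q2 > Thr, join the
   highest pair and recompute Q2 on the full TF-pair distribution.
   Unmerged, internally dissimilar units recurse to the next level
   (families → subfamilies → TFs). The result is a partition of all TFs;
   UPGMA-scheme similarity trees (with Q2 join heights) can be exported
   as Newick.

## Worked example

A synthetic collection with planted branch structure (24 TFs in 2
classes × 3 families; within-family motifs share a consensus):

```r
library(tfbranch)

g  <- generate_planted_collection(synth_config(seed = 42))
sc <- score_pairs(g$collection, compare_config(seed = 42))
br <- find_branches(g$collection, sc)
as.data.frame(br)[, c("branch_id", "class", "level", "members", "n_tfs", "internal_q2")]
#>   branch_id class  level members n_tfs internal_q2
#> 1      B001   1.1 family   1.1.1     4    3.000434
#> 2      B002   1.1 family   1.1.2     4    3.000434
#> 3      B003   1.1 family   1.1.3     4    3.000434
#> 4      B004   1.2 family   1.2.1     4    3.000434
#> 5      B005   1.2 family   1.2.2     4    3.000434
#> 6      B006   1.2 family   1.2.3     4    3.000434
recovery_score(br, g$truth)
#> [1] 1
```

Each planted family comes back as one family-level branch
(`internal_q2 = 3.0004` is the cap `log10(1001)` of the default
1000-decoy permutation null: every within-family TF pair beats all
decoys). The partition matches the planted truth exactly (adjusted Rand
index 1).

Individual comparisons under the exact null give uncapped,
database-scale scores:

```r
pool <- as_pool(g$collection)
m <- g$collection$motifs
motif_score(m[["TF_1_1_1_1.M1"]], m[["TF_1_1_1_2.M1"]], pool,
            compare_config(null_mode = "dp_exact"))
#> <tfb_pairscore> score 3.811 (p = 0.000155), offset -2 (-), raw 5.586
motif_score(m[["TF_1_1_1_1.M1"]], m[["TF_2_3_2_1.M1"]], pool,
            compare_config(null_mode = "dp_exact"))
#> <tfb_pairscore> score 0.772 (p = 0.169), offset 1 (+), raw 3.522
```

The first pair (same planted family, found on the minus strand at
offset −2) is significantly similar (3.81 > 3); the cross-class pair is
not (0.77). Family-level heatmap values:

```r
fam <- group_units(g$collection$tfs, "family")
similarity_matrix(fam[1:3], sc)
#> <tfb_simmatrix> Q2 metric:
#>       1.1.1 1.1.2 1.1.3
#> 1.1.1  3.00  0.38  0.48
#> 1.1.2  0.38  3.00  0.30
#> 1.1.3  0.48  0.30  3.00
```

`run_pipeline()` wires everything together and writes pair scores,
per-level Q2 matrices, the branch table, the merge log, per-class Newick
trees, the heterogeneous-TF report and a JSON run manifest. The same
pipeline is scriptable via `inst/cli/tfbranch.R`
(`synth` / `compare` / `branches` subcommands).

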
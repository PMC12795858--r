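---
title: "Branches of binding-site motif similarity in the TF DBD hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Branches of binding-site motif similarity in the TF DBD hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfbranch)
```

## The problem

The structural classification of transcription factors by their
DNA-binding domain assigns every TF a dotted path — superclass, class,
family and (sometimes) subfamily, e.g. `{1.1.1.1}` for the Jun
subfamily of the bZIP class. Binding-site motif collections built from
in vivo and in vitro experiments attach one or more 4×L frequency
matrices to each TF. The correspondence between the two is uneven:
superclasses are always heterogeneous, some whole classes share one
recognizable motif, and elsewhere similarity only appears at the family
or subfamily level — or not at all. `tfbranch` makes that structure
explicit by partitioning the hierarchy into *branches*: maximal sets of
sister units in which the majority of TF pairs have significantly
similar motifs.

## The motif-pair score

For motifs $M_i, M_j$ the package enumerates every gapless alignment
offset with at least `min_overlap` aligned columns, on both strands
(the stored orientation of a motif is arbitrary). Each offset's raw
score is the sum over aligned columns of the Pearson correlation
between the two frequency 4-vectors; a uniform column has zero variance
and is scored 0, since an uninformative column carries no similarity
evidence. The best raw score is converted to a p-value and

$$\mathrm{Score}(M_i, M_j) = -\log_{10} p,$$

with *significant similarity* defined strictly as
$\mathrm{Score} > Thr = 3$ (i.e. $p < 10^{-3}$). A score of exactly 3.0
(p = 0.001) is *not* significant.

Two null models are implemented:

* **permutation** (default for testing): `n_null` decoy targets of the
  target's length are assembled by resampling columns, with
  replacement, from the pool of all columns in the collection; the
  estimator $p = (1+k)/(1+N)$ counts decoys whose best alignment is at
  least as good. It never returns 0, and it caps scores at
  $\log_{10}(N+1)$ — with the default $N = 1000$ a perfect exceedance
  gives 3.0004, just above the threshold. Reproducing database-scale
  scores (> 6) requires `dp_exact` or an impractically large `n_null`.
* **dp_exact**: the score of each query column against the pool is
  discretized into `n_bins` histogram bins on $[-1, 1]$; the per-offset
  null of the summed column score under column-independence is obtained
  by convolution, the observed sum is binned identically, and offsets
  are combined by $p = 1 - (1 - p_{\min})^{n_\text{offsets}}$, clamped
  to $[10^{-300}, 1]$. On targets small enough to enumerate, this
  equals brute-force enumeration of all column assignments exactly
  (same binning), and lies within one discretization bin of the
  continuous enumeration — both are asserted in the test suite.

Scores are symmetrized by evaluating both query/target directions and
keeping the larger score, because all downstream metrics treat TF pairs
symmetrically. Per-pair RNG streams are derived from the base seed and
the two motif identifiers, so results are independent of evaluation
order and cacheable.

## TF-pair, per-TF and set metrics

A TF pair (X, Y) is summarized over the $N_X \times N_Y$ motif-pair
score distribution. The aggregator is configurable; the default is
**max**: two TFs are similar if *any* of their motif variants match.
This choice is consistent with branches always carrying all motif
variants of their member TFs, and median/min/quartiles are available
for sensitivity analysis.

One TF's motif **heterogeneity** is the median of its
$N(N-1)/2$ intra-motif pair scores (undefined for $N = 1$).
`flag_heterogeneous_tfs()` lists multi-motif TFs whose heterogeneity
fails the threshold — TFs whose own motif variants are significantly
different.

Two TF sets with K and T members are compared through the
$K(K-1)/2$ (intra) or $K \cdot T$ (inter) TF-pair score distribution,
summarized by Min, Q1, Q2, Q3 and Max (linear interpolation between
order statistics, the most common quantile convention). Q2 is the
primary metric: Q2 > Thr means more than half of all TF pairs are
significantly similar. Degenerate intra-set cases: a lone multi-motif
TF falls back to its heterogeneity distribution (so a one-TF family
still gets an internal similarity value), and a lone single-motif TF
has no distribution at all — its cell is `NA`, rendered distinctly and
never counted as above or below the threshold.

## Branch finding

Branches never span classes (superclasses are computed and reported but
are too heterogeneous to form branches). Per class:

1. If the intra-class Q2 exceeds Thr, the whole class is one branch.
2. Otherwise sister families are merged greedily: while any pair of
   current clusters has inter-set Q2 > Thr, the highest-valued pair is
   joined and all pairwise values are recomputed *on the full TF-pair
   distribution of the merged sets*. A family that already exceeds Thr
   internally stays eligible for merging; clusters are final only when
   no pair qualifies.
3. Multi-unit clusters become branches. An unmerged family with
   internal Q2 > Thr becomes a branch on its own. Remaining families
   recurse identically over subfamilies, then over single TFs; a TF
   nothing joins becomes a singleton branch.

Merging happens among sister units of one level only — a family cannot
merge with a lone subfamily of another family — matching how the
procedure is applied in practice. Ties in the merge value are broken by
lexicographic order of unit paths, making the partition deterministic.
The merge log records every accepted join with its value; the test
suite asserts that every multi-unit branch arises only through merges
above the threshold and that the result is always a partition of the
TF set.

Unions are not re-tested after merging: a cluster formed through
above-threshold joins is kept even if the internal Q2 of the union
falls below Thr. (The greedy criterion is the *inter-set* Q2 between
current branches, which is what the selection step tests against the
threshold.)

`agglomerate()` builds the full UPGMA-scheme similarity tree over any
unit list with the same recomputed-Q2 linkage (not Lance–Williams
averaging), regardless of the threshold. `export_newick()` renders it
with edge lengths `child Q2 − parent Q2`, clamped at 0: similarity
normally *decreases* from leaves to root, but a unit whose internal Q2
is below the value at which it merged (e.g. a family less coherent than
its union with a sister family) produces a "reversed" path; such edges
are clamped to zero length and flagged in the `reversals` attribute.

## The synthetic world

`generate_planted_collection()` emulates a motif collection with known
branch structure so every part of the method is testable offline:

* Hierarchy: 2 classes × 3 families × 2 subfamilies × 2 TFs by default
  (24 TFs), one superclass. Each *family* is a planted branch.
* Motifs per TF: 1–4 with probabilities (0.6, 0.3, 0.1, 0) — most TFs
  in real collections carry one or two motif variants.
* Consensus matrices: per branch, length 8–12 (typical eukaryotic TFBS
  model lengths), columns drawn from a sparse Dirichlet(0.3, …) so they
  are peaked like real PWM columns.
* Member motifs: columns drawn from
  $\mathrm{Dirichlet}\big((\kappa_\text{in} - 1)\,c + 1\big)$ around
  the consensus column $c$. The offset parameterization makes
  $\kappa_\text{in} = 1$ *exactly* the flat Dirichlet(1,1,1,1) used for
  unrelated motifs — the within-branch signal vanishes entirely, which
  the calibration tests rely on — while $\kappa_\text{in} \to \infty$
  recovers the consensus. Members are shifted by ±1–2 columns with
  probability 0.3 and reverse complemented with probability 0.3, so the
  aligner's offset/strand search is exercised.
* Heterogeneous TFs: with probability 0.1 a multi-motif TF draws one
  motif from a different branch's consensus, emulating TFs with
  genuinely dissimilar motif variants.

What a green planted-recovery test establishes: with strong
within-branch similarity ($\kappa_\text{in} = 32$) the pipeline
recovers the planted family partition (ARI ≥ 0.9 in ≥ 95 % of seeds).
What it does not establish: the generator's columns are independent
(no dinucleotide structure), lengths are homogeneous, the hierarchy is
balanced, and the branch signal is binary (present/absent) — real
collections have graded similarity across families, unbalanced class
sizes and motif-length variation, so quantitative results on real
databases are not implied.

## Numerical choices

* Threshold comparisons are strict (`> Thr`) everywhere.
* Quartiles: linear interpolation (type 7); verified against an
  independent sort-and-index oracle.
* Pearson of 4-vectors with zero variance → 0; negative frequencies are
  an error.
* `min_overlap` defaults to 4 to avoid spurious one-column matches
  (configurable down to 1).
* dp_exact combination is clamped to $[10^{-300}, 1]$; exactness of the
  multiple-offset correction is not claimed (offsets overlap, so
  independence is an approximation).
* The permutation estimator's tie rule counts decoys within $10^{-12}$
  of the observed raw as exceedances, keeping self-comparisons stable.
* Per-pair seeds are a 31-bit polynomial hash of the sorted id pair
  added to the base seed, so any evaluation order and any cache layout
  give identical scores.

## Known limitations

* The TF-pair aggregator of the pair metric is not uniquely determined
  by the method's published description; `max` is the package's default
  with alternatives exposed in `metric_config()`.
* Permutation-mode branch finding at the default `n_null = 1000`
  depends on zero-exceedance pairs (score 3.0004 > 3); collections with
  weak signal should use `dp_exact`.
* No E-values, no query-centric FDR, no gapped motif alignment, no
  sequence scanning, and no re-derivation of the DBD hierarchy itself.
* Heatmap/tree outputs are TSV and Newick; graphical rendering is left
  to standard tools (`pheatmap`, `ape`).
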
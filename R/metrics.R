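## TF-pair, per-TF and set-set similarity metrics built on motif-pair
## scores: quartile summaries of the pair-score distributions.

#' Metric configuration
#'
#' @param thr Significance threshold on the -log10 p-value scale
#'   (default 3, i.e. p < 0.001); comparisons are strict (`> thr`).
#' @param tf_pair_aggregator How the N_X x N_Y motif-pair scores of a TF
#'   pair collapse to one value.  Default `"max"`: two TFs are similar if
#'   any of their motif variants match (every branch carries all motif
#'   variants of its TFs).
#' @param set_metric Which quartile of the TF-pair score distribution
#'   summarizes a set pair; `"q2"` (the median) is the primary metric.
#' @return A list of class `tfb_metric_config`.
#' @export
metric_config <- function(thr = 3,
                          tf_pair_aggregator = c("max", "median", "min",
                                                 "q1", "q3"),
                          set_metric = c("q2", "min", "q1", "q3", "max")) {
  if (thr <= 0) stop("thr must be > 0")
  structure(list(thr = thr,
                 tf_pair_aggregator = match.arg(tf_pair_aggregator),
                 set_metric = match.arg(set_metric)),
            class = "tfb_metric_config")
}

#' Is a similarity score significant?
#'
#' Strict comparison against the threshold: a score exactly at `thr`
#' (e.g. 3.0 from p = 0.001 at the conventional threshold) is NOT
#' significant.
#'
#' @param score Numeric score(s) on the -log10 p scale (`NA` allowed).
#' @param cfg A [metric_config()].
#' @return Logical vector; `NA` scores give `FALSE`.
#' @export
is_similar <- function(score, cfg = metric_config())
  !is.na(score) & score > cfg$thr

# quartile summaries use linear interpolation between order statistics
five_num <- function(x) {
  if (!length(x)) return(rep(NA_real_, 5L))
  quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
}

aggregate_scores <- function(x, how) {
  switch(how,
         max = max(x), min = min(x),
         median = quantile(x, 0.5, type = 7, names = FALSE),
         q1 = quantile(x, 0.25, type = 7, names = FALSE),
         q3 = quantile(x, 0.75, type = 7, names = FALSE))
}

# all symmetrized scores between the motifs of two TFs (N_X x N_Y values)
tf_pair_values <- function(X, Y, scores) {
  vals <- numeric(0)
  for (a in X$motif_ids)
    for (b in Y$motif_ids)
      vals <- c(vals, get_score(scores, a, b))
  vals
}

#' Similarity of a TF pair
#'
#' Aggregates the `N_X x N_Y` motif-pair scores of the two TFs into a
#' single similarity value.
#'
#' @param X,Y `tfb_tfrecord` objects.
#' @param scores A `tfb_scores` lookup covering all their motif pairs.
#' @param cfg A [metric_config()].
#' @return Non-negative numeric score.
#' @export
tf_pair_score <- function(X, Y, scores, cfg = metric_config()) {
  aggregate_scores(tf_pair_values(X, Y, scores), cfg$tf_pair_aggregator)
}

#' Motif heterogeneity of one TF
#'
#' Median of the `N (N - 1) / 2` pairwise scores among the TF's own
#' motifs; `NA` for a single-motif TF (empty distribution).  A TF whose
#' heterogeneity does not exceed `thr` carries significantly different
#' binding-site motifs.
#'
#' @param X A `tfb_tfrecord`.
#' @inheritParams tf_pair_score
#' @return Numeric median score, or `NA`.
#' @export
tf_heterogeneity <- function(X, scores, cfg = metric_config()) {
  ids <- X$motif_ids
  if (length(ids) < 2L) return(NA_real_)
  prs <- combn(ids, 2L)
  vals <- vapply(seq_len(ncol(prs)),
                 function(k) get_score(scores, prs[1L, k], prs[2L, k]),
                 0)
  quantile(vals, 0.5, type = 7, names = FALSE)
}

#' Quartile similarity metrics of one or two TF sets
#'
#' Builds the TF-pair score distribution -- all `K (K - 1) / 2` unordered
#' pairs within `A`, or all `K x T` pairs between `A` and `B` -- with each
#' pair valued by [tf_pair_score()], and summarizes it by the five metrics
#' Min, Q1, Q2 (median), Q3, Max.
#'
#' Degenerate intra-set cases: a single TF with several motifs falls back
#' to that TF's [tf_heterogeneity()] distribution (its intra-TF motif
#' pairs); a single TF with a single motif has no pair distribution and
#' all five metrics are `NA`.
#'
#' @param A List of `tfb_tfrecord` (non-empty).
#' @param B Optional second list; `NULL` means intra-set.
#' @inheritParams tf_pair_score
#' @return Object of class `tfb_set_similarity`: `min`, `q1`, `q2`, `q3`,
#'   `max`, `n_pairs`, `kind` (`"intra"`/`"inter"`).
#' @export
set_similarity <- function(A, B = NULL, scores, cfg = metric_config()) {
  if (!length(A)) stop("set A is empty")
  if (is.null(B)) {
    if (length(A) == 1L) {
      X <- A[[1L]]
      ids <- X$motif_ids
      if (length(ids) < 2L)
        return(new_set_similarity(rep(NA_real_, 5L), 0L, "intra"))
      prs <- combn(ids, 2L)
      vals <- vapply(seq_len(ncol(prs)),
                     function(k) get_score(scores, prs[1L, k], prs[2L, k]),
                     0)
      return(new_set_similarity(five_num(vals), ncol(prs), "intra"))
    }
    prs <- combn(length(A), 2L)
    vals <- vapply(seq_len(ncol(prs)), function(k)
      tf_pair_score(A[[prs[1L, k]]], A[[prs[2L, k]]], scores, cfg), 0)
    new_set_similarity(five_num(vals), ncol(prs), "intra")
  } else {
    if (!length(B)) stop("set B is empty")
    vals <- numeric(0)
    for (X in A) for (Y in B)
      vals <- c(vals, tf_pair_score(X, Y, scores, cfg))
    new_set_similarity(five_num(vals), length(A) * length(B), "inter")
  }
}

new_set_similarity <- function(q, n_pairs, kind)
  structure(list(min = q[1L], q1 = q[2L], q2 = q[3L], q3 = q[4L],
                 max = q[5L], n_pairs = as.integer(n_pairs), kind = kind),
            class = "tfb_set_similarity")

#' @export
print.tfb_set_similarity <- function(x, ...) {
  cat(sprintf(
    "<tfb_set_similarity> %s, %d pairs: Min %.2f Q1 %.2f Q2 %.2f Q3 %.2f Max %.2f\n",
    x$kind, x$n_pairs, x$min, x$q1, x$q2, x$q3, x$max))
  invisible(x)
}

#' Set-similarity matrix over disjoint hierarchy units
#'
#' Diagonal cells hold the intra-set metrics of each unit; off-diagonal
#' cells the inter-set metrics.  A diagonal `NA` marks a unit with a
#' single TF carrying a single motif.
#'
#' @param units Named list; each element is a list of `tfb_tfrecord`.
#'   Units must be pairwise disjoint in TF names.
#' @inheritParams tf_pair_score
#' @return Object of class `tfb_simmatrix`: one symmetric numeric matrix
#'   per metric (`min`, `q1`, `q2`, `q3`, `max`) plus `n_pairs`.
#' @export
similarity_matrix <- function(units, scores, cfg = metric_config()) {
  if (is.null(names(units)) || any(names(units) == ""))
    stop("units must be named")
  tfn <- lapply(units, function(u) vapply(u, function(r) r$name, ""))
  if (anyDuplicated(unlist(tfn)))
    stop("units overlap in TF: ", unlist(tfn)[duplicated(unlist(tfn))][1L])
  n <- length(units)
  mats <- lapply(1:6, function(i) {
    m <- matrix(NA_real_, n, n, dimnames = list(names(units), names(units)))
    m
  })
  names(mats) <- c("min", "q1", "q2", "q3", "max", "n_pairs")
  for (i in seq_len(n)) {
    s <- set_similarity(units[[i]], NULL, scores, cfg)
    for (f in names(mats))
      mats[[f]][i, i] <- s[[if (f == "n_pairs") "n_pairs" else f]]
    if (i < n) for (j in seq(i + 1L, n)) {
      s <- set_similarity(units[[i]], units[[j]], scores, cfg)
      for (f in names(mats)) {
        v <- s[[if (f == "n_pairs") "n_pairs" else f]]
        mats[[f]][i, j] <- v
        mats[[f]][j, i] <- v
      }
    }
  }
  structure(mats, class = "tfb_simmatrix")
}

#' @export
print.tfb_simmatrix <- function(x, ...) {
  cat("<tfb_simmatrix> Q2 metric:\n")
  print(round(x$q2, 2))
  invisible(x)
}
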
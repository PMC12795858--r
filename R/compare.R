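## Motif-pair comparison: -log10 p-value of the best gapless alignment
## under a per-column Pearson comparison function, TomTom-style.

#' Comparison configuration
#'
#' @param min_overlap Minimum number of aligned columns per offset
#'   (default 4; set to 1 for strict parity with single-column matching).
#' @param strands `"both"` compares against the target and its reverse
#'   complement (motif orientation in databases is arbitrary); `"forward"`
#'   compares one strand only.
#' @param null_mode `"permutation"` draws decoy targets by resampling pool
#'   columns (scores capped at `log10(n_null + 1)`); `"dp_exact"` computes
#'   the per-offset null of the summed column score exactly by convolution
#'   over a discretized score histogram.
#' @param n_null Number of permutation decoys (>= 100).
#' @param n_bins Histogram bins over the column-score range \[-1, 1\] in
#'   `dp_exact` mode.
#' @param seed Base seed; per-pair streams are derived from it and the
#'   motif identifiers so caching order cannot change results.
#' @param pseudocount Pseudocount used when normalizing counts.
#' @return A list of class `tfb_compare_config`.
#' @export
compare_config <- function(min_overlap = 4L, strands = c("both", "forward"),
                           null_mode = c("permutation", "dp_exact"),
                           n_null = 1000L, n_bins = 100L, seed = 1L,
                           pseudocount = 0) {
  strands <- match.arg(strands)
  null_mode <- match.arg(null_mode)
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  if (null_mode == "permutation" && n_null < 100L)
    stop("n_null must be >= 100 in permutation mode")
  if (n_bins < 2L) stop("n_bins must be >= 2")
  structure(list(min_overlap = as.integer(min_overlap), strands = strands,
                 null_mode = null_mode, n_null = as.integer(n_null),
                 n_bins = as.integer(n_bins), seed = as.integer(seed),
                 pseudocount = pseudocount),
            class = "tfb_compare_config")
}

#' Pearson column score of two frequency 4-vectors
#'
#' Sample Pearson correlation of two base-frequency columns; defined as 0
#' when either column is uniform (zero variance), since an uninformative
#' column carries no similarity evidence.
#'
#' @param p,q Numeric 4-vectors summing to 1.
#' @return Real in \[-1, 1\].
#' @export
column_score <- function(p, q) {
  if (any(p < 0) || any(q < 0)) stop("negative frequencies")
  cpp_col_pearson(as.numeric(p), as.numeric(q))
}

#' Reverse complement of a motif
#'
#' Reverses column order and swaps A with T and C with G within each
#' column.  An involution.
#'
#' @param m A `tfb_motif` or a 4 x L matrix.
#' @return Same type as the input.
#' @export
reverse_complement <- function(m) {
  rc <- function(mat) {
    out <- mat[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(mat))), drop = FALSE]
    rownames(out) <- BASES
    out
  }
  if (inherits(m, "tfb_motif")) {
    m$mat <- rc(m$mat)
    m
  } else rc(as.matrix(m))
}

#' Best gapless alignment of two motifs
#'
#' Enumerates all offsets with at least `min_overlap` aligned columns on
#' the configured strands; the raw score of an offset is the sum of
#' [column_score()] over the aligned columns.
#'
#' @param query,target `tfb_motif` objects.
#' @param cfg A [compare_config()].
#' @return List with `raw`, `offset` (target position of query column 1,
#'   0-based, in the reported orientation), `orientation` (`"+"`/`"-"`),
#'   and `n_offsets` (configurations enumerated, both strands counted).
#' @export
best_alignment <- function(query, target, cfg = compare_config()) {
  q <- motif_freq(query, cfg$pseudocount)
  t <- motif_freq(target, cfg$pseudocount)
  res <- cpp_best_alignment(q, t, cfg$min_overlap, cfg$strands == "both")
  list(raw = res$raw, offset = res$offset,
       orientation = if (res$strand > 0) "+" else "-",
       n_offsets = res$n_offsets)
}

# deterministic 31-bit stream seed from the base seed and a string key
derive_seed <- function(seed, key) {
  h <- 0
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' Directional motif comparison p-value
#'
#' Significance of the best gapless alignment of `query` against `target`
#' under a null of targets with columns drawn from `pool`.  In
#' `permutation` mode, `n_null` decoy targets of the target's length are
#' resampled from the pool and `p = (1 + k) / (1 + n_null)` where `k`
#' decoys align at least as well as the observed target (the estimator
#' never returns 0).  In `dp_exact` mode, the per-offset null of the
#' summed column score is computed by convolution of discretized
#' per-column score histograms, and offsets are combined by
#' `p = 1 - (1 - p_min)^n_offsets`, clamped to \[1e-300, 1\].
#'
#' @param query,target `tfb_motif` objects.
#' @param pool 4 x P matrix of frequency columns (normally all columns of
#'   the collection), or a `tfb_collection`.
#' @param cfg A [compare_config()].
#' @return List of class `tfb_pairscore`: `score` (-log10 p), `p_value`,
#'   `offset`, `orientation`, `raw`, `n_offsets`.
#' @export
motif_pvalue <- function(query, target, pool, cfg = compare_config()) {
  pool <- as_pool(pool, cfg$pseudocount)
  if (ncol(pool) < 1L) stop("empty column pool")
  q <- motif_freq(query, cfg$pseudocount)
  t <- motif_freq(target, cfg$pseudocount)
  both <- cfg$strands == "both"
  al <- cpp_best_alignment(q, t, cfg$min_overlap, both)
  if (cfg$null_mode == "permutation") {
    if (cfg$n_null < 1L) stop("n_null must be >= 1")
    set.seed(derive_seed(cfg$seed, paste(query$id, target$id, sep = "\r")))
    raws <- cpp_null_best_raws(q, ncol(t), pool, cfg$n_null,
                               cfg$min_overlap, both)
    k <- sum(raws >= al$raw - 1e-12)
    p <- (1 + k) / (1 + cfg$n_null)
  } else {
    dp <- cpp_dp_pvalue(q, t, pool, cfg$min_overlap, both, cfg$n_bins)
    p <- dp$p_value
  }
  structure(list(score = -log10(p), p_value = p, offset = al$offset,
                 orientation = if (al$strand > 0) "+" else "-",
                 raw = al$raw, n_offsets = al$n_offsets),
            class = "tfb_pairscore")
}

#' Symmetrized motif-pair similarity score
#'
#' Evaluates [motif_pvalue()] in both directions and returns the result
#' with the larger score, so that `motif_score(a, b)` equals
#' `motif_score(b, a)`.  A pair is called significantly similar when
#' `score > thr` (strict inequality; the conventional threshold is 3,
#' i.e. p < 0.001).
#'
#' @inheritParams motif_pvalue
#' @param a,b `tfb_motif` objects.
#' @return A `tfb_pairscore` (see [motif_pvalue()]).
#' @export
motif_score <- function(a, b, pool, cfg = compare_config()) {
  # evaluate in canonical id order so the derived RNG stream is shared
  if (a$id > b$id) { tmp <- a; a <- b; b <- tmp }
  ab <- motif_pvalue(a, b, pool, cfg)
  ba <- motif_pvalue(b, a, pool, cfg)
  if (ba$score > ab$score) ba else ab
}

#' @export
print.tfb_pairscore <- function(x, ...) {
  cat(sprintf(
    "<tfb_pairscore> score %.3f (p = %.3g), offset %d (%s), raw %.3f\n",
    x$score, x$p_value, x$offset, x$orientation, x$raw))
  invisible(x)
}

#' Pool of frequency columns of a collection
#' @param x A `tfb_collection` or a 4 x P matrix.
#' @param pseudocount Passed to [motif_freq()].
#' @return 4 x P matrix of column frequencies.
#' @export
as_pool <- function(x, pseudocount = 0) {
  if (inherits(x, "tfb_collection"))
    return(do.call(cbind, lapply(x$motifs, motif_freq,
                                 pseudocount = pseudocount)))
  x <- as.matrix(x)
  if (nrow(x) != 4L) stop("pool must be a 4 x P matrix")
  x
}

## ---------------------------------------------------------------------------
## batch scoring and lookup

#' Score a set of motif pairs
#'
#' Computes the symmetrized [motif_score()] for each requested pair.  The
#' null pool is always the full collection.  Per-pair RNG streams are
#' derived from `cfg$seed` and the two motif ids, so the result does not
#' depend on the order in which pairs are evaluated.
#'
#' @param collection An annotated `tfb_collection`.
#' @param cfg A [compare_config()].
#' @param pairs `"within_class"` (default) scores every unordered motif
#'   pair whose TFs share a class -- all that branch finding needs;
#'   `"within_superclass"` additionally covers class-vs-class comparisons
#'   inside each superclass; `"all"` scores every unordered pair; or a
#'   2-column character matrix of motif ids.
#' @return A `tfb_scores` object: data.frame (`motif_a`, `motif_b`, `raw`,
#'   `offset`, `orientation`, `p_value`, `score`) with a constant-time
#'   pair lookup used by the metric functions.
#' @export
score_pairs <- function(collection, cfg = compare_config(),
                        pairs = c("within_class", "within_superclass",
                                  "all")) {
  pool <- as_pool(collection, cfg$pseudocount)
  if (is.character(pairs) && is.null(dim(pairs))) {
    pairs <- match.arg(pairs)
    ids <- names(collection$motifs)
    pm <- if (pairs == "all") {
      if (length(ids) < 2L) matrix(character(), 0, 2)
      else t(combn(ids, 2L))
    } else {
      if (is.null(collection$tfs))
        stop("'", pairs, "' pair selection needs an annotated collection")
      cls <- motif_class_key(collection,
                             if (pairs == "within_class") 2L else 1L)
      do.call(rbind, lapply(split(ids, cls[ids]), function(g) {
        if (length(g) < 2L) matrix(character(), 0, 2) else t(combn(g, 2L))
      }))
    }
  } else pm <- as.matrix(pairs)
  n <- nrow(pm)
  out <- data.frame(motif_a = character(n), motif_b = character(n),
                    raw = numeric(n), offset = integer(n),
                    orientation = character(n), p_value = numeric(n),
                    score = numeric(n), stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    a <- collection$motifs[[pm[i, 1L]]]
    b <- collection$motifs[[pm[i, 2L]]]
    if (is.null(a) || is.null(b))
      stop("unknown motif id in pair list: ", pm[i, 1L], " / ", pm[i, 2L])
    ps <- motif_score(a, b, pool, cfg)
    out[i, ] <- list(a$id, b$id, ps$raw, ps$offset, ps$orientation,
                     ps$p_value, ps$score)
  }
  scores_lookup(out)
}

# hierarchy prefix of the TF owning each motif, named by motif id
motif_class_key <- function(collection, depth = 2L) {
  unlist(unname(lapply(collection$tfs, function(r)
    setNames(rep(path_prefix(r$path, depth), length(r$motif_ids)),
             r$motif_ids))))
}

#' Build a score lookup from a pair-score table
#' @param df data.frame with columns `motif_a`, `motif_b`, `score`.
#' @return A `tfb_scores` object.
#' @export
scores_lookup <- function(df) {
  env <- new.env(parent = emptyenv(), size = max(16L, 2L * nrow(df)))
  for (i in seq_len(nrow(df))) {
    a <- df$motif_a[i]; b <- df$motif_b[i]
    key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
    assign(key, df$score[i], envir = env)
  }
  structure(list(table = df, env = env), class = "tfb_scores")
}

#' Look up a symmetrized motif-pair score
#' @param scores A `tfb_scores` object.
#' @param a,b Motif ids.
#' @return Numeric score; errors if the pair was never scored.
#' @export
get_score <- function(scores, a, b) {
  key <- if (a <= b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  v <- get0(key, envir = scores$env, inherits = FALSE)
  if (is.null(v)) stop("no score available for motif pair ", a, " / ", b)
  v
}

#' @export
print.tfb_scores <- function(x, ...) {
  cat("<tfb_scores> ", nrow(x$table), " motif pairs\n", sep = "")
  invisible(x)
}
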
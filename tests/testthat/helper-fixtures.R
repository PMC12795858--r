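# Fixture builders shared across test files.  Everything is generated in
# code; no binary fixtures.

# one-hot-ish matrix from a base string, e.g. peak_mat("ACGT"); `soft`
# spreads a little mass on the other bases so columns are informative but
# not degenerate
peak_mat <- function(bases, soft = 0.06) {
  idx <- match(strsplit(bases, "")[[1]], c("A", "C", "G", "T"))
  stopifnot(!anyNA(idx))
  m <- matrix(soft / 3, 4, length(idx))
  for (j in seq_along(idx)) m[idx[j], j] <- 1 - soft
  rownames(m) <- c("A", "C", "G", "T")
  m
}

peak_motif <- function(id, bases, tf_name = id, soft = 0.06)
  motif(id, peak_mat(bases, soft), tf_name = tf_name, is_counts = FALSE)

# pool of random informative columns (Dirichlet(0.5) draws)
random_pool <- function(P, alpha = 0.5) {
  vapply(seq_len(P), function(i) {
    x <- rgamma(4, alpha)
    x / sum(x)
  }, numeric(4))
}

# fabricated symmetric score lookup from explicit triples
fake_scores <- function(a, b, score)
  scores_lookup(data.frame(motif_a = a, motif_b = b,
                           raw = 0, offset = 0L, orientation = "+",
                           p_value = 10^-score, score = score,
                           stringsAsFactors = FALSE))

# single-motif TF with a fabricated motif id equal to its name
fake_tf <- function(name, path = "1.1.1.1", motif_ids = name)
  tf_record(name, path, motif_ids)

# independent quartile oracle: explicit sort + linear interpolation
# between order statistics (kept free of stats::quantile on purpose)
oracle_quartiles <- function(x) {
  x <- sort(x)
  n <- length(x)
  one <- function(p) {
    if (n == 1) return(x[1])
    h <- (n - 1) * p
    lo <- floor(h)
    x[lo + 1] + (h - lo) * (x[min(lo + 2, n)] - x[lo + 1])
  }
  c(min = x[1], q1 = one(0.25), q2 = one(0.5), q3 = one(0.75), max = x[n])
}

# build a tfb_collection of single-motif TFs from a named list of paths
fake_collection <- function(paths, bases = NULL) {
  nms <- names(paths)
  motifs <- lapply(seq_along(nms), function(i) {
    b <- if (is.null(bases)) paste(rep("ACGT", 2), collapse = "") else bases[[i]]
    peak_motif(nms[i], b, tf_name = nms[i])
  })
  annot <- data.frame(motif_id = nms, tf_name = nms,
                      path = unlist(paths), stringsAsFactors = FALSE)
  attach_annotation(motif_collection(motifs), annot)
}
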
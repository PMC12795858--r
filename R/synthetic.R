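## Seeded generator of motif collections with planted branch structure:
## one consensus frequency matrix per planted branch, member motifs drawn
## column-wise from Dirichlet(kappa_in * consensus), unrelated motifs
## across branches.

#' Synthetic collection configuration
#'
#' The generator emulates a DBD-style hierarchy (one superclass;
#' `n_classes` classes of `families_per_class` families, each with
#' `subfamilies_per_family` subfamilies of `tfs_per_subfamily` TFs) in
#' which each unit at `branch_level` is a planted branch: its TFs share a
#' consensus motif, perturbed per motif by Dirichlet column noise of
#' concentration `kappa_in`, optional 1-2 column shifts and reverse
#' complementation.  TFs of different branches get motifs from
#' independent consensus matrices.
#'
#' @param n_classes,families_per_class,subfamilies_per_family,tfs_per_subfamily
#'   Hierarchy shape (defaults 2, 3, 2, 2: 24 TFs).
#' @param motifs_per_tf_probs Probabilities of a TF carrying 1-4 motifs
#'   (default `c(0.6, 0.3, 0.1, 0)`; databases mostly hold one or two
#'   motif variants per TF).
#' @param motif_length Inclusive range of motif lengths (default 8-12,
#'   typical of eukaryotic TFBS models).
#' @param kappa_in Dirichlet concentration multiplier within a branch;
#'   large values give near-identical motifs, 1 makes within-branch
#'   motifs indistinguishable from unrelated ones.
#' @param shift_prob Probability a member motif is shifted by 1-2 columns
#'   against the consensus.
#' @param revcomp_prob Probability a member motif is stored reverse
#'   complemented.
#' @param hetero_tf_prob Probability that a multi-motif TF draws one
#'   motif from a different branch's consensus (emulating TFs with
#'   genuinely dissimilar motif variants).
#' @param branch_level Level whose units are the planted branches
#'   (`"family"` or `"subfamily"`).
#' @param seed Integer seed; the collection is a deterministic function
#'   of the config.
#' @return A list of class `tfb_synth_config`.
#' @export
synth_config <- function(n_classes = 2L, families_per_class = 3L,
                         subfamilies_per_family = 2L,
                         tfs_per_subfamily = 2L,
                         motifs_per_tf_probs = c(0.6, 0.3, 0.1, 0),
                         motif_length = c(8L, 12L), kappa_in = 32,
                         shift_prob = 0.3, revcomp_prob = 0.3,
                         hetero_tf_prob = 0.1,
                         branch_level = c("family", "subfamily"),
                         seed = 1L) {
  branch_level <- match.arg(branch_level)
  stopifnot(n_classes >= 1, families_per_class >= 1,
            subfamilies_per_family >= 1, tfs_per_subfamily >= 1,
            length(motifs_per_tf_probs) == 4L,
            all(motifs_per_tf_probs >= 0),
            sum(motifs_per_tf_probs) > 0,
            length(motif_length) == 2L,
            motif_length[1L] >= 4L, motif_length[2L] >= motif_length[1L],
            kappa_in > 0,
            shift_prob >= 0, shift_prob <= 1,
            revcomp_prob >= 0, revcomp_prob <= 1,
            hetero_tf_prob >= 0, hetero_tf_prob <= 1)
  structure(as.list(environment()), class = "tfb_synth_config")
}

# one Dirichlet draw of dimension length(alpha)
rdirichlet1 <- function(alpha) {
  x <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(x == 0)) x[sample.int(length(alpha), 1L)] <- 1
  x / sum(x)
}

# peaked PWM-like consensus: per column a Dirichlet(0.3) draw, which
# concentrates mass on one or two bases as real binding motifs do
random_consensus <- function(L) {
  vapply(seq_len(L), function(j) rdirichlet1(rep(0.3, 4)), numeric(4))
}

#' Generate a motif collection with planted branches
#'
#' @param cfg A [synth_config()].
#' @return List with `collection` (annotated `tfb_collection`), `truth`
#'   (named character vector TF -> planted branch label), and
#'   `annotation` (the motif/TF/path table as a data.frame).
#' @export
generate_planted_collection <- function(cfg = synth_config()) {
  set.seed(cfg$seed)
  Lpad <- 4L  # consensus padding so shifted windows stay inside
  branch_of <- function(cl, fa, sf)
    if (cfg$branch_level == "family") paste(1, cl, fa, sep = ".")
    else paste(1, cl, fa, sf, sep = ".")

  # consensus per planted branch, drawn up-front in deterministic order
  branch_keys <- character(0)
  for (cl in seq_len(cfg$n_classes))
    for (fa in seq_len(cfg$families_per_class)) {
      if (cfg$branch_level == "family")
        branch_keys <- c(branch_keys, branch_of(cl, fa, NA))
      else for (sf in seq_len(cfg$subfamilies_per_family))
        branch_keys <- c(branch_keys, branch_of(cl, fa, sf))
    }
  consensus <- lapply(branch_keys, function(k) {
    L <- sample(seq(cfg$motif_length[1L], cfg$motif_length[2L]), 1L)
    random_consensus(L + 2L * Lpad)
  })
  names(consensus) <- branch_keys

  draw_member <- function(bkey) {
    cons <- consensus[[bkey]]
    L <- ncol(cons) - 2L * Lpad
    shift <- 0L
    if (runif(1) < cfg$shift_prob)
      shift <- sample(c(-2L, -1L, 1L, 2L), 1L)
    win <- cons[, seq(Lpad + 1L + shift, Lpad + L + shift), drop = FALSE]
    # concentration (kappa - 1) * consensus + 1: at kappa_in = 1 this is
    # the flat Dirichlet(1,1,1,1) used for unrelated motifs (within-branch
    # signal vanishes entirely); as kappa_in grows the column converges to
    # the consensus
    mat <- vapply(seq_len(L), function(j)
      rdirichlet1((cfg$kappa_in - 1) * win[, j] + 1), numeric(4))
    if (runif(1) < cfg$revcomp_prob) mat <- reverse_complement(mat)
    mat
  }

  motifs <- list(); annot <- list(); truth <- character(0)
  for (cl in seq_len(cfg$n_classes)) {
    for (fa in seq_len(cfg$families_per_class)) {
      for (sf in seq_len(cfg$subfamilies_per_family)) {
        bkey <- branch_of(cl, fa, sf)
        path <- paste(1, cl, fa, sf, sep = ".")
        for (t in seq_len(cfg$tfs_per_subfamily)) {
          tf <- sprintf("TF_%d_%d_%d_%d", cl, fa, sf, t)
          nm <- sample.int(4L, 1L, prob = cfg$motifs_per_tf_probs)
          hetero <- nm >= 2L && runif(1) < cfg$hetero_tf_prob
          for (k in seq_len(nm)) {
            src <- bkey
            if (hetero && k == nm) {
              others <- setdiff(branch_keys, bkey)
              if (length(others)) src <- sample(others, 1L)
            }
            id <- sprintf("%s.M%d", tf, k)
            motifs[[length(motifs) + 1L]] <-
              motif(id, draw_member(src), tf_name = tf,
                    source = "synthetic", is_counts = FALSE)
            annot[[length(annot) + 1L]] <-
              data.frame(motif_id = id, tf_name = tf, path = path,
                         stringsAsFactors = FALSE)
          }
          truth[tf] <- bkey
        }
      }
    }
  }
  annot <- do.call(rbind, annot)
  coll <- attach_annotation(motif_collection(motifs), annot)
  list(collection = coll, truth = truth, annotation = annot)
}

#' Adjusted Rand Index between two partitions
#'
#' Chance-corrected agreement between a found branch partition and the
#' planted truth: 1 for identical partitions, approximately 0 for
#' independent ones.
#'
#' @param found A `tfb_branches` object or a named character/factor
#'   vector (element name -> cluster label).
#' @param truth Named vector over the same TF universe.
#' @return ARI in \[-1, 1\].
#' @export
recovery_score <- function(found, truth) {
  if (inherits(found, "tfb_branches")) found <- branch_assignment(found)
  if (is.null(names(found)) || is.null(names(truth)))
    stop("partitions must be named vectors")
  if (!setequal(names(found), names(truth)))
    stop("partitions are over different TF universes")
  f <- as.character(found[names(truth)])
  t <- as.character(truth)
  tab <- table(f, t)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  denom <- (sum_a + sum_b) / 2 - expected
  if (denom == 0) return(ifelse(sum_ij == expected, 1, 0))
  (sum_ij - expected) / denom
}
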
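## Branch finding: partition each class of the DBD hierarchy into maximal
## sets of sister units whose TF-pair similarity median exceeds the
## threshold, plus UPGMA-scheme similarity trees.

# depth per level: how many path numerals identify a unit
LEVEL_DEPTH <- c(class = 2L, family = 3L, subfamily = 4L, tf = 5L)

#' Group TF records into sister units at a hierarchy level
#'
#' A TF whose path does not reach the level (e.g. a TF without a
#' subfamily) forms its own pseudo-unit, and the `"tf"` level always
#' yields one unit per TF.
#'
#' @param records List of `tfb_tfrecord`.
#' @param level One of `"class"`, `"family"`, `"subfamily"`, `"tf"`.
#' @return Named list of units (each a list of records), keyed by the
#'   dotted path prefix.
#' @export
group_units <- function(records, level) {
  depth <- LEVEL_DEPTH[[level]]
  keys <- vapply(records, function(r) {
    if (level == "tf")
      return(paste0(paste(unclass(r$path), collapse = "."), ".tf:", r$name))
    p <- path_prefix(r$path, depth)
    if (is.na(p))
      paste0(paste(unclass(r$path), collapse = "."), ".tf:", r$name)
    else p
  }, "")
  split(records, keys)
}

# metric value used for merge decisions (default the median, Q2)
merge_value <- function(s, cfg) s[[cfg$set_metric]]

# Greedy agglomeration over sister units: repeatedly join the pair of
# current clusters with the highest inter-set metric while it exceeds
# thr, recomputing the metric on the full TF-pair distribution after
# every merge.  Ties broken lexicographically by cluster keys.
greedy_merge <- function(units, scores, cfg) {
  clusters <- lapply(names(units), function(k) k)
  recs_of <- function(keys) unlist(lapply(keys, function(k) units[[k]]),
                                   recursive = FALSE)
  log <- list()
  repeat {
    n <- length(clusters)
    if (n < 2L) break
    best <- NULL
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      v <- merge_value(set_similarity(recs_of(clusters[[i]]),
                                      recs_of(clusters[[j]]),
                                      scores, cfg), cfg)
      if (is.na(v) || v <= cfg$thr) next
      ki <- min(clusters[[i]]); kj <- min(clusters[[j]])
      key <- if (ki <= kj) c(ki, kj) else c(kj, ki)
      if (is.null(best) || v > best$v + 1e-12 ||
          (abs(v - best$v) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L])))) {
        best <- list(i = i, j = j, v = v, key = key)
      }
    }
    if (is.null(best)) break
    log[[length(log) + 1L]] <- data.frame(
      step = length(log) + 1L,
      cluster_a = paste(sort(clusters[[best$i]]), collapse = "+"),
      cluster_b = paste(sort(clusters[[best$j]]), collapse = "+"),
      value = best$v, stringsAsFactors = FALSE)
    merged <- sort(c(clusters[[best$i]], clusters[[best$j]]))
    clusters <- c(clusters[-c(best$i, best$j)], list(merged))
  }
  list(clusters = clusters,
       log = if (length(log)) do.call(rbind, log)
             else data.frame(step = integer(), cluster_a = character(),
                             cluster_b = character(), value = numeric()))
}

#' Partition the hierarchy into branches of motif-similar TFs
#'
#' Works class by class (branches never span classes; superclasses are
#' too heterogeneous to form branches).  For each class: if the
#' intra-class metric exceeds `thr` the whole class is one branch;
#' otherwise sister families are greedily merged while some pair of
#' current clusters has an inter-set metric above `thr` (the metric is
#' recomputed over the full TF-pair distribution after every merge).
#' Multi-unit clusters become branches; an unmerged family whose internal
#' metric exceeds `thr` becomes a branch; the remaining families recurse
#' identically over their subfamilies and finally over single TFs, which
#' end as singleton branches if nothing joins them.  Every TF lands in
#' exactly one branch.
#'
#' @param collection An annotated `tfb_collection`, or a list of
#'   `tfb_tfrecord` (every TF must be annotated at least to class level).
#' @param scores A `tfb_scores` lookup covering all motif pairs within
#'   each class (see [score_pairs()]).
#' @param cfg A [metric_config()]; merges use its `set_metric` (Q2 by
#'   default) with the strict threshold `thr`.
#' @return Object of class `tfb_branches`: a data.frame with one row per
#'   branch (`branch_id`, `class`, `level`, `members`, `tfs`, `n_tfs`,
#'   `internal_q2`), with attributes `merge_log` (data.frame of all
#'   accepted merges) and `assignment` (named vector TF -> branch_id).
#' @export
find_branches <- function(collection, scores, cfg = metric_config()) {
  records <- as_records(collection)
  depths <- vapply(records, function(r) length(unclass(r$path)), 0L)
  if (any(depths < 2L))
    stop("TF '", records[[which(depths < 2L)[1L]]]$name,
         "' is not annotated to class level")
  classes <- group_units(records, "class")
  branches <- list()
  logs <- list()

  add_branch <- function(level, members, recs, class_key) {
    s <- set_similarity(recs, NULL, scores, cfg)
    branches[[length(branches) + 1L]] <<- list(
      class = class_key, level = level,
      members = paste(sort(members), collapse = ";"),
      tfs = vapply(recs, function(r) r$name, ""),
      internal_q2 = s$q2)
  }

  descend <- function(recs, level, class_key) {
    units <- group_units(recs, level)
    next_level <- switch(level, family = "subfamily", subfamily = "tf",
                         tf = NULL)
    if (length(units) >= 2L) {
      gm <- greedy_merge(units, scores, cfg)
      if (nrow(gm$log)) {
        gm$log$class <- class_key; gm$log$level <- level
        logs[[length(logs) + 1L]] <<- gm$log
      }
      clusters <- gm$clusters
    } else clusters <- lapply(names(units), function(k) k)
    for (cl in clusters) {
      crecs <- unlist(lapply(cl, function(k) units[[k]]),
                      recursive = FALSE)
      if (length(cl) > 1L) {
        add_branch(level, cl, crecs, class_key)
      } else {
        s <- set_similarity(crecs, NULL, scores, cfg)
        v <- merge_value(s, cfg)
        if (!is.na(v) && v > cfg$thr) {
          add_branch(level, cl, crecs, class_key)
        } else if (is.null(next_level)) {
          add_branch("tf", cl, crecs, class_key)   # singleton branch
        } else {
          descend(crecs, next_level, class_key)
        }
      }
    }
  }

  for (ck in sort(names(classes))) {
    recs <- classes[[ck]]
    s <- set_similarity(recs, NULL, scores, cfg)
    v <- merge_value(s, cfg)
    if (!is.na(v) && v > cfg$thr && length(recs) > 1L) {
      add_branch("class", ck, recs, ck)
    } else if (length(recs) == 1L) {
      descend(recs, "tf", ck)
    } else {
      descend(recs, "family", ck)
    }
  }

  df <- do.call(rbind, lapply(seq_along(branches), function(i) {
    b <- branches[[i]]
    data.frame(branch_id = sprintf("B%03d", i), class = b$class,
               level = b$level, members = b$members,
               tfs = paste(sort(b$tfs), collapse = ";"),
               n_tfs = length(b$tfs), internal_q2 = b$internal_q2,
               stringsAsFactors = FALSE)
  }))
  assignment <- unlist(lapply(seq_along(branches), function(i)
    setNames(rep(sprintf("B%03d", i), length(branches[[i]]$tfs)),
             branches[[i]]$tfs)))
  all_tfs <- vapply(records, function(r) r$name, "")
  if (length(assignment) != length(all_tfs) ||
      anyDuplicated(names(assignment)) ||
      !setequal(names(assignment), all_tfs))
    stop("internal error: branches do not partition the TF set")
  structure(df, class = c("tfb_branches", "data.frame"),
            merge_log = if (length(logs)) do.call(rbind, logs)
                        else data.frame(step = integer(),
                                        cluster_a = character(),
                                        cluster_b = character(),
                                        value = numeric(),
                                        class = character(),
                                        level = character()),
            assignment = assignment[order(names(assignment))])
}

as_records <- function(x) {
  if (inherits(x, "tfb_collection")) {
    if (is.null(x$tfs)) stop("collection has no TF annotation")
    return(x$tfs)
  }
  if (is.list(x) && all(vapply(x, inherits, TRUE, "tfb_tfrecord"))) {
    names(x) <- vapply(x, function(r) r$name, "")
    return(x)
  }
  stop("expected a tfb_collection or a list of tfb_tfrecord")
}

#' Merge log of a branch partition
#' @param branches A `tfb_branches` object.
#' @return data.frame of accepted merges (`step`, `cluster_a`,
#'   `cluster_b`, `value`, `class`, `level`).
#' @export
merge_log <- function(branches) attr(branches, "merge_log")

#' TF-to-branch assignment of a branch partition
#' @param branches A `tfb_branches` object.
#' @return Named character vector, TF name -> branch id.
#' @export
branch_assignment <- function(branches) attr(branches, "assignment")

#' TFs with significantly dissimilar motif variants
#'
#' Lists TFs carrying two or more motifs whose pairwise-score median
#' ([tf_heterogeneity()]) does not exceed `thr` -- i.e. TFs for which the
#' motif variants themselves are not significantly similar.
#'
#' @inheritParams find_branches
#' @return data.frame (`tf_name`, `n_motifs`, `heterogeneity`), sorted by
#'   ascending heterogeneity.
#' @export
flag_heterogeneous_tfs <- function(collection, scores,
                                   cfg = metric_config()) {
  records <- as_records(collection)
  rows <- lapply(records, function(r) {
    if (length(r$motif_ids) < 2L) return(NULL)
    h <- tf_heterogeneity(r, scores, cfg)
    if (h > cfg$thr) return(NULL)
    data.frame(tf_name = r$name, n_motifs = length(r$motif_ids),
               heterogeneity = h, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(tf_name = character(), n_motifs = integer(),
                      heterogeneity = numeric()))
  out[order(out$heterogeneity), , drop = FALSE]
}

## ---------------------------------------------------------------------------
## similarity trees

#' UPGMA-scheme similarity tree over sister units
#'
#' Repeatedly joins the pair of current clusters with the highest
#' inter-cluster metric (Q2 by default), recomputed on the full TF-pair
#' distribution between the merged sets -- not by Lance-Williams
#' averaging -- until one cluster remains.  The full tree is returned
#' regardless of the threshold; node heights are the similarity values at
#' which the children merged.
#'
#' @param units Named list of units (each a list of `tfb_tfrecord`), at
#'   least 2.
#' @inheritParams find_branches
#' @return Object of class `tfb_tree` with fields `merge` (hclust-style
#'   merge matrix), `height` (metric value at each join), `labels`, and
#'   `leaf_intra` (internal metric of each leaf unit, possibly `NA`).
#' @export
agglomerate <- function(units, scores, cfg = metric_config()) {
  n <- length(units)
  if (n < 2L) stop("need at least 2 units")
  labels <- names(units)
  # active clusters: list of (node id, member unit indices); leaves are -i
  active <- lapply(seq_len(n), function(i) list(node = -i, idx = i))
  recs_of <- function(idx) unlist(units[idx], recursive = FALSE)
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  for (step in seq_len(n - 1L)) {
    best <- NULL
    m <- length(active)
    for (i in seq_len(m - 1L)) for (j in seq(i + 1L, m)) {
      v <- merge_value(set_similarity(recs_of(active[[i]]$idx),
                                      recs_of(active[[j]]$idx),
                                      scores, cfg), cfg)
      if (is.na(v)) next
      ki <- min(labels[active[[i]]$idx]); kj <- min(labels[active[[j]]$idx])
      key <- if (ki <= kj) c(ki, kj) else c(kj, ki)
      if (is.null(best) || v > best$v + 1e-12 ||
          (abs(v - best$v) <= 1e-12 &&
           (key[1L] < best$key[1L] ||
            (key[1L] == best$key[1L] && key[2L] < best$key[2L]))))
        best <- list(i = i, j = j, v = v, key = key)
    }
    if (is.null(best))
      stop("all inter-cluster similarities are NA; cannot agglomerate")
    merge[step, ] <- c(active[[best$i]]$node, active[[best$j]]$node)
    height[step] <- best$v
    joined <- list(node = step,
                   idx = c(active[[best$i]]$idx, active[[best$j]]$idx))
    active <- c(active[-c(best$i, best$j)], list(joined))
  }
  leaf_intra <- vapply(units, function(u)
    set_similarity(u, NULL, scores, cfg)$q2, 0)
  structure(list(merge = merge, height = height, labels = labels,
                 leaf_intra = leaf_intra),
            class = "tfb_tree")
}

#' @export
print.tfb_tree <- function(x, ...) {
  cat("<tfb_tree> ", length(x$labels), " leaves, join heights: ",
      paste(round(x$height, 2), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Export a similarity tree as Newick text
#'
#' Similarity decreases from the leaves toward the root, so the edge
#' above a node has length `node height - parent height`, clamped at 0.
#' A clamped edge (a unit whose internal similarity is below the value at
#' which it merged -- the tree path "reverses direction") is recorded in
#' the `reversals` attribute.
#'
#' @param tree A `tfb_tree`.
#' @return Character scalar of Newick text (with trailing `;`), with
#'   attribute `reversals` naming clamped child nodes.
#' @export
export_newick <- function(tree) {
  n <- length(tree$labels)
  reversals <- character(0)
  safe <- function(s) gsub("[ ():;,'\\[\\]]", "_", s)
  node_str <- function(node, parent_h) {
    if (node < 0) {
      lab <- tree$labels[-node]
      h <- tree$leaf_intra[-node]
      if (is.na(h)) h <- parent_h
      len <- h - parent_h
      if (len < 0) {
        reversals <<- c(reversals, lab)
        len <- 0
      }
      sprintf("%s:%.6g", safe(lab), len)
    } else {
      h <- tree$height[node]
      len <- if (is.na(parent_h)) 0 else h - parent_h
      lab <- paste0("n", node)
      if (len < 0) {
        reversals <<- c(reversals, lab)
        len <- 0
      }
      sprintf("(%s,%s)%s:%.6g",
              node_str(tree$merge[node, 1L], h),
              node_str(tree$merge[node, 2L], h),
              lab, len)
    }
  }
  root <- n - 1L
  txt <- paste0("(",
                node_str(tree$merge[root, 1L], tree$height[root]), ",",
                node_str(tree$merge[root, 2L], tree$height[root]),
                ");")
  attr(txt, "reversals") <- reversals
  txt
}
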
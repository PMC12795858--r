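## End-to-end orchestration: scores -> metric matrices -> branches ->
## trees -> reports, with a machine-readable run manifest.

#' Run the full branch-finding pipeline
#'
#' Reads (or accepts) an annotated motif collection, computes all
#' within-class motif-pair scores, the set-similarity matrices at each
#' hierarchy level, the branch partition, per-class family trees, and the
#' heterogeneous-TF report, writing everything as TSV/Newick/JSON under
#' `out_dir`.
#'
#' @param x An annotated `tfb_collection`, or a motif file path (then
#'   `annotation` is required).
#' @param out_dir Output directory (created if missing).
#' @param annotation Annotation TSV path or data.frame (when `x` is a
#'   file path or an unannotated collection).
#' @param dialect Motif dialect for [read_motifs()].
#' @param compare_cfg A [compare_config()].
#' @param metric_cfg A [metric_config()].
#' @param scores Optional precomputed `tfb_scores` (cache reuse); when
#'   supplied it must cover all within-superclass pairs.
#' @return Invisibly, a list with `collection`, `scores`, `branches`,
#'   `heterogeneous`, `matrices`, `trees` and `manifest`.
#' @export
run_pipeline <- function(x, out_dir, annotation = NULL,
                         dialect = "jaspar_pfm",
                         compare_cfg = compare_config(),
                         metric_cfg = metric_config(),
                         scores = NULL) {
  if (is.character(x)) x <- read_motifs(x, dialect)
  if (!inherits(x, "tfb_collection")) stop("x must be a collection or path")
  if (is.null(x$tfs)) {
    if (is.null(annotation)) stop("an unannotated collection needs 'annotation'")
    if (is.character(annotation)) annotation <- read_annotation(annotation)
    x <- attach_annotation(x, annotation)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  # within_superclass also covers the class-vs-class heatmap cells
  if (is.null(scores)) scores <- score_pairs(x, compare_cfg,
                                             "within_superclass")
  write.table(scores$table, file.path(out_dir, "pair_scores.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  records <- x$tfs
  matrices <- list()
  for (level in c("class", "family", "subfamily")) {
    units <- group_units(records, level)
    # sister units share a parent: classes are grouped per superclass,
    # families/subfamilies per class
    depth <- if (level == "class") 1L else 2L
    per_class <- split(names(units),
                       vapply(names(units), function(k)
                         paste(strsplit(k, ".", fixed = TRUE)[[1L]][
                           seq_len(depth)], collapse = "."), ""))
    for (ck in names(per_class)) {
      u <- units[per_class[[ck]]]
      if (length(u) < 1L) next
      sm <- similarity_matrix(u, scores, metric_cfg)
      matrices[[paste(level, ck, sep = ":")]] <- sm
      write.table(round(sm$q2, 4),
                  file.path(out_dir, sprintf("simmatrix_%s_class%s_q2.tsv",
                                             level, ck)),
                  sep = "\t", quote = FALSE, col.names = NA)
    }
  }

  branches <- find_branches(x, scores, metric_cfg)
  write.table(as.data.frame(branches), file.path(out_dir, "branches.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(merge_log(branches), file.path(out_dir, "merge_log.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  hetero <- flag_heterogeneous_tfs(x, scores, metric_cfg)
  write.table(hetero, file.path(out_dir, "heterogeneous_tfs.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  trees <- list()
  for (ck in sort(unique(vapply(records, function(r)
    path_prefix(r$path, 2L), "")))) {
    crecs <- Filter(function(r) path_prefix(r$path, 2L) == ck, records)
    units <- group_units(crecs, "family")
    if (length(units) < 2L) next
    tr <- agglomerate(units, scores, metric_cfg)
    nwk <- export_newick(tr)
    writeLines(nwk, file.path(out_dir, sprintf("tree_class%s.nwk", ck)))
    trees[[ck]] <- tr
  }

  manifest <- list(
    package = "tfbranch",
    version = as.character(utils::packageVersion("tfbranch")),
    n_motifs = length(x$motifs), n_tfs = length(x$tfs),
    n_pairs_scored = nrow(scores$table),
    n_branches = nrow(branches),
    compare = unclass(compare_cfg), metric = unclass(metric_cfg))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(list(collection = x, scores = scores, branches = branches,
                 heterogeneous = hetero, matrices = matrices,
                 trees = trees, manifest = manifest))
}
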
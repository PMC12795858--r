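#' @useDynLib tfbranch, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median quantile setNames rgamma runif
#' @importFrom utils read.delim write.table combn
NULL

BASES <- c("A", "C", "G", "T")

#' Construct a motif
#'
#' A motif is a 4 x L matrix of per-position nucleotide counts or
#' frequencies over A, C, G, T, plus an identifier and the name of the
#' transcription factor it belongs to.  The matrix is kept as supplied
#' (counts are preserved); [motif_freq()] returns the column-stochastic
#' form.
#'
#' @param id Motif identifier, unique within a collection.
#' @param mat 4 x L numeric matrix, rows A, C, G, T, entries >= 0.
#' @param tf_name Name of the owning TF (defaults to `id`).
#' @param source Free-text collection label.
#' @param is_counts Logical; whether `mat` holds counts rather than
#'   frequencies.  Only affects how the motif is written out.
#' @return An object of class `tfb_motif`.
#' @export
motif <- function(id, mat, tf_name = id, source = "unknown", is_counts = NA) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L)
    stop("motif '", id, "': matrix must have 4 rows (A,C,G,T), got ",
         nrow(mat))
  if (ncol(mat) < 1L) stop("motif '", id, "': length must be >= 1")
  if (any(!is.finite(mat)) || any(mat < 0))
    stop("motif '", id, "': entries must be finite and non-negative")
  rownames(mat) <- BASES
  if (is.na(is_counts))
    is_counts <- any(mat > 1 + 1e-9) ||
      all(abs(colSums(mat) - 1) > 1e-6)
  structure(list(id = id, tf_name = tf_name, mat = mat,
                 source = source, is_counts = is_counts),
            class = "tfb_motif")
}

#' @export
print.tfb_motif <- function(x, ...) {
  cat("<tfb_motif> ", x$id, " (TF ", x$tf_name, "), L = ", ncol(x$mat),
      if (x$is_counts) ", counts" else ", frequencies", "\n", sep = "")
  print(round(x$mat, 3))
  invisible(x)
}

#' Motif length
#' @param m A `tfb_motif`.
#' @return Integer number of columns.
#' @export
motif_length <- function(m) ncol(m$mat)

#' Column-stochastic frequency matrix of a motif
#'
#' @param m A `tfb_motif`.
#' @param pseudocount Pseudocount added to every cell before column
#'   normalization (default 0; comparison uses Pearson correlation which
#'   tolerates zeros).
#' @return 4 x L matrix with columns summing to 1.
#' @export
motif_freq <- function(m, pseudocount = 0)
  normalize_counts(m$mat, pseudocount = pseudocount)

#' Normalize a count matrix to column frequencies
#'
#' Column j becomes `(c_ij + pseudocount) / (sum_i c_ij + 4 * pseudocount)`.
#' Idempotent on an already column-stochastic matrix (with pseudocount 0).
#'
#' @param mat 4 x L non-negative matrix.
#' @param pseudocount Non-negative real added to each cell.
#' @return 4 x L column-stochastic matrix.
#' @export
normalize_counts <- function(mat, pseudocount = 0) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4L) stop("matrix must have 4 rows")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  tot <- colSums(mat) + 4 * pseudocount
  if (any(tot == 0))
    stop("all-zero column with pseudocount 0 (column ",
         which(tot == 0)[1L], ")")
  sweep(mat + pseudocount, 2L, tot, "/")
}

## ---------------------------------------------------------------------------
## hierarchy paths

#' Parse a dotted TFClass-style hierarchy path
#'
#' Paths follow the DBD classification nomenclature: up to four dotted
#' numerals for superclass, class, family and subfamily (the subfamily may
#' be absent), e.g. `"1.1.1.1"` or `"2.3.0"`.
#'
#' @param x Character scalar like `"1.1.1.1"`, optionally wrapped in
#'   curly braces.
#' @return An object of class `tfb_path`: integer vector of 1-4 numerals.
#' @export
hierarchy_path <- function(x) {
  if (inherits(x, "tfb_path")) return(x)
  s <- gsub("[{} ]", "", as.character(x))
  parts <- strsplit(s, ".", fixed = TRUE)[[1L]]
  if (length(parts) < 1L || length(parts) > 4L || any(parts == "") ||
      any(is.na(suppressWarnings(as.integer(parts)))))
    stop("malformed hierarchy path: '", x, "'")
  structure(as.integer(parts), class = "tfb_path")
}

#' @export
format.tfb_path <- function(x, ...)
  paste0("{", paste(unclass(x), collapse = "."), "}")

#' @export
print.tfb_path <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Dotted prefix of a hierarchy path
#' @param path A `tfb_path`.
#' @param depth 1 = superclass, 2 = class, 3 = family, 4 = subfamily.
#' @return Character key like `"1.1.1"`, or `NA` if the path is shallower
#'   than `depth`.
#' @export
path_prefix <- function(path, depth) {
  v <- unclass(hierarchy_path(path))
  if (length(v) < depth) return(NA_character_)
  paste(v[seq_len(depth)], collapse = ".")
}

## ---------------------------------------------------------------------------
## TF records and collections

#' Construct a TF record
#'
#' @param name TF name.
#' @param path `tfb_path` (or parseable string) locating the TF in the
#'   DBD hierarchy; must reach at least the class level.
#' @param motif_ids Character vector of motif identifiers (N >= 1).
#' @return An object of class `tfb_tfrecord`.
#' @export
tf_record <- function(name, path, motif_ids) {
  path <- hierarchy_path(path)
  if (length(motif_ids) < 1L) stop("TF '", name, "' has no motifs")
  structure(list(name = name, path = path,
                 motif_ids = as.character(motif_ids)),
            class = "tfb_tfrecord")
}

#' Assemble a motif collection
#'
#' @param motifs List of `tfb_motif` (ids must be unique).
#' @param tfs Optional list of `tfb_tfrecord`; every motif must belong to
#'   exactly one TF.
#' @param background Base composition 4-vector (sums to 1).
#' @return An object of class `tfb_collection`.
#' @export
motif_collection <- function(motifs, tfs = NULL,
                             background = rep(0.25, 4)) {
  ids <- vapply(motifs, function(m) m$id, "")
  if (anyDuplicated(ids))
    stop("duplicate motif id: ", ids[duplicated(ids)][1L])
  names(motifs) <- ids
  if (abs(sum(background) - 1) > 1e-6)
    stop("background must sum to 1")
  if (!is.null(tfs)) {
    names(tfs) <- vapply(tfs, function(r) r$name, "")
    used <- unlist(lapply(tfs, function(r) r$motif_ids))
    if (anyDuplicated(used))
      stop("motif assigned to more than one TF: ",
           used[duplicated(used)][1L])
    missing <- setdiff(used, ids)
    if (length(missing))
      stop("annotation refers to unknown motif id: ", missing[1L])
  }
  structure(list(motifs = motifs, tfs = tfs, background = background),
            class = "tfb_collection")
}

#' @export
print.tfb_collection <- function(x, ...) {
  cat("<tfb_collection> ", length(x$motifs), " motifs",
      if (!is.null(x$tfs)) paste0(", ", length(x$tfs), " TFs"),
      "\n", sep = "")
  invisible(x)
}

## ---------------------------------------------------------------------------
## parsers

#' Read a motif collection
#'
#' Supported dialects:
#' \describe{
#'   \item{`jaspar_pfm`}{`>id name` header followed by four rows
#'     `A [ 1 2 3 ]` (counts; bracket-free rows also accepted).}
#'   \item{`meme_minimal`}{MEME minimal text: `MOTIF id` blocks with a
#'     `letter-probability matrix` of L rows x 4 columns (frequencies).}
#'   \item{`hocomoco_pcm`}{`>id` header followed by L whitespace-separated
#'     rows of 4 counts (positions as rows, columns A C G T).}
#' }
#' Rows are canonicalized to A, C, G, T order; counts are preserved and
#' normalized lazily through [motif_freq()].
#'
#' @param path File path.
#' @param dialect One of `"jaspar_pfm"`, `"meme_minimal"`, `"hocomoco_pcm"`.
#' @param source Collection label stored on each motif (defaults to the
#'   file name).
#' @return A `tfb_collection` (without TF annotation).
#' @export
read_motifs <- function(path,
                        dialect = c("jaspar_pfm", "meme_minimal",
                                    "hocomoco_pcm"),
                        source = basename(path)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  motifs <- switch(dialect,
                   jaspar_pfm = parse_jaspar(lines, source),
                   meme_minimal = parse_meme(lines, source),
                   hocomoco_pcm = parse_pcm(lines, source))
  if (!length(motifs)) stop("no motifs found in ", path)
  motif_collection(motifs)
}

parse_num_fields <- function(s) {
  s <- gsub("[][]", " ", s)
  v <- strsplit(trimws(s), "[ \t]+")[[1L]]
  suppressWarnings(as.numeric(v[v != ""]))
}

parse_jaspar <- function(lines, source) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no JASPAR headers ('>') found")
  bounds <- c(hdr, length(lines) + 1L)
  motifs <- list()
  for (k in seq_along(hdr)) {
    head_parts <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "[ \t]+")[[1L]]
    id <- head_parts[1L]
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[trimws(body) != ""]
    if (length(body) != 4L)
      stop("motif '", id, "': expected 4 matrix rows, got ", length(body))
    row_base <- toupper(substr(trimws(body), 1L, 1L))
    vals <- lapply(body, function(b)
      parse_num_fields(sub("^\\s*[ACGTacgt]\\s*", "", b)))
    lens <- lengths(vals)
    if (length(unique(lens)) != 1L || any(vapply(vals, anyNA, TRUE)))
      stop("motif '", id, "': ragged or non-numeric matrix rows")
    mat <- do.call(rbind, vals)
    if (all(row_base %in% BASES) && !anyDuplicated(row_base)) {
      mat <- mat[match(BASES, row_base), , drop = FALSE]
    }
    motifs[[k]] <- motif(id, mat, source = source, is_counts = TRUE)
  }
  motifs
}

parse_meme <- function(lines, source) {
  mstart <- grep("^MOTIF\\b", lines)
  if (!length(mstart)) stop("no 'MOTIF' blocks found")
  motifs <- list()
  for (k in seq_along(mstart)) {
    head_parts <- strsplit(trimws(lines[mstart[k]]), "[ \t]+")[[1L]]
    id <- head_parts[2L]
    if (is.na(id)) stop("MOTIF line without an identifier")
    lpm <- grep("^letter-probability matrix", lines)
    lpm <- lpm[lpm > mstart[k]][1L]
    if (is.na(lpm)) stop("motif '", id, "': no letter-probability matrix")
    w <- suppressWarnings(as.integer(
      sub(".*\\bw\\s*=\\s*([0-9]+).*", "\\1", lines[lpm])))
    rows <- list(); i <- lpm + 1L
    while (i <= length(lines)) {
      tl <- trimws(lines[i])
      if (tl == "" || grepl("^(MOTIF|URL|letter-probability)", lines[i])) break
      rows[[length(rows) + 1L]] <- parse_num_fields(tl)
      i <- i + 1L
    }
    if (!is.na(w)) rows <- rows[seq_len(min(length(rows), w))]
    if (!length(rows)) stop("motif '", id, "': empty matrix")
    if (any(lengths(rows) != 4L))
      stop("motif '", id, "': matrix rows must have 4 entries")
    mat <- t(do.call(rbind, rows))   # positions are rows in MEME
    motifs[[length(motifs) + 1L]] <-
      motif(id, mat, source = source, is_counts = FALSE)
  }
  motifs
}

parse_pcm <- function(lines, source) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no PCM headers ('>') found")
  bounds <- c(hdr, length(lines) + 1L)
  motifs <- list()
  for (k in seq_along(hdr)) {
    id <- strsplit(sub("^>\\s*", "", lines[hdr[k]]), "[ \t]+")[[1L]][1L]
    body <- lines[seq(hdr[k] + 1L, bounds[k + 1L] - 1L)]
    body <- body[trimws(body) != ""]
    if (!length(body)) stop("motif '", id, "': empty matrix")
    rows <- lapply(body, parse_num_fields)
    if (any(lengths(rows) != 4L) || any(vapply(rows, anyNA, TRUE)))
      stop("motif '", id, "': each position row must have 4 counts")
    mat <- t(do.call(rbind, rows))   # positions are rows in PCM files
    motifs[[k]] <- motif(id, mat, source = source, is_counts = TRUE)
  }
  motifs
}

## ---------------------------------------------------------------------------
## writers (round-trip support)

#' Write a motif collection
#'
#' @param collection A `tfb_collection`.
#' @param path Output file.
#' @param dialect Same dialects as [read_motifs()].  Count dialects write
#'   the stored matrix verbatim; `meme_minimal` writes frequencies.
#' @return `path`, invisibly.
#' @export
write_motifs <- function(collection, path,
                         dialect = c("jaspar_pfm", "meme_minimal",
                                     "hocomoco_pcm")) {
  dialect <- match.arg(dialect)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- function(x) sub("\\.?0+$", "", sprintf("%.10f", x))
  if (dialect == "meme_minimal") {
    writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
                 "strands: + -", ""), con)
  }
  for (m in collection$motifs) {
    mat <- if (dialect == "meme_minimal") motif_freq(m) else m$mat
    if (dialect == "jaspar_pfm") {
      writeLines(paste0(">", m$id, " ", m$tf_name), con)
      for (i in 1:4)
        writeLines(paste0(BASES[i], " [ ",
                          paste(fmt(mat[i, ]), collapse = " "), " ]"), con)
    } else if (dialect == "hocomoco_pcm") {
      writeLines(paste0(">", m$id), con)
      for (j in seq_len(ncol(mat)))
        writeLines(paste(fmt(mat[, j]), collapse = "\t"), con)
    } else {
      writeLines(paste0("MOTIF ", m$id), con)
      writeLines(sprintf(
        "letter-probability matrix: alength= 4 w= %d nsites= 20 E= 0",
        ncol(mat)), con)
      for (j in seq_len(ncol(mat)))
        writeLines(paste(" ", paste(fmt(mat[, j]), collapse = "  ")), con)
      writeLines("", con)
    }
  }
  invisible(path)
}

## ---------------------------------------------------------------------------
## annotation

#' Read a TF hierarchy annotation table
#'
#' Tab-separated table with columns `motif_id`, `tf_name`, `path` mapping
#' each motif to its TF and the TF's dotted hierarchy path.
#'
#' @param path TSV file path.
#' @return data.frame with character columns `motif_id`, `tf_name`, `path`.
#' @export
read_annotation <- function(path) {
  df <- read.delim(path, header = TRUE, stringsAsFactors = FALSE,
                   colClasses = "character")
  need <- c("motif_id", "tf_name", "path")
  if (!all(need %in% names(df)))
    stop("annotation must have columns: ", paste(need, collapse = ", "))
  df[, need]
}

#' Attach TF annotation to a motif collection
#'
#' Groups motifs by TF name, parses hierarchy paths, and validates that
#' every annotated motif exists, every TF has one consistent path, and
#' (optionally) that every motif is annotated.
#'
#' @param collection A `tfb_collection`.
#' @param annot data.frame as returned by [read_annotation()].
#' @param require_complete Error when some motif lacks annotation.
#' @return The collection with `$tfs` populated; each motif's `tf_name`
#'   is updated from the annotation.
#' @export
attach_annotation <- function(collection, annot, require_complete = TRUE) {
  missing <- setdiff(annot$motif_id, names(collection$motifs))
  if (length(missing))
    stop("annotation refers to unknown motif id: ", missing[1L])
  if (require_complete) {
    un <- setdiff(names(collection$motifs), annot$motif_id)
    if (length(un)) stop("motif without annotation: ", un[1L])
  }
  tfs <- lapply(split(annot, annot$tf_name), function(g) {
    paths <- unique(g$path)
    if (length(paths) != 1L)
      stop("conflicting hierarchy paths for TF '", g$tf_name[1L], "': ",
           paste(paths, collapse = " vs "))
    tf_record(g$tf_name[1L], hierarchy_path(paths), g$motif_id)
  })
  tfs <- tfs[order(names(tfs))]
  for (r in tfs)
    for (id in r$motif_ids) collection$motifs[[id]]$tf_name <- r$name
  motif_collection(collection$motifs, tfs, collection$background)
}

#' Dump a collection as a long-format TSV (one row per motif column)
#' @param collection A `tfb_collection`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
dump_collection_tsv <- function(collection, path) {
  rows <- do.call(rbind, lapply(collection$motifs, function(m) {
    f <- motif_freq(m)
    data.frame(motif_id = m$id, tf_name = m$tf_name,
               pos = seq_len(ncol(f)), A = f[1, ], C = f[2, ],
               G = f[3, ], T = f[4, ], row.names = NULL)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
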
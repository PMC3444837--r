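# FASTA ingest and writers for the pipeline's tabular / tree outputs.

IUPAC_DNA <- c("A", "C", "G", "T", "R", "Y", "S", "W", "K", "M",
               "B", "D", "H", "V", "N")

#' Validate and construct a sequence set
#'
#' A sequence set is a named character vector of upper-case DNA sequences.
#' Names are the sequence ids; their order is preserved and defines the row
#' order of every downstream matrix.  Residues must be IUPAC DNA codes
#' (`ACGT`, the ambiguity letters `RYSWKMBDHVN`); lower-case input is folded
#' to upper case.
#'
#' @param x named character vector of DNA sequences.
#' @return the validated vector, classed `"sequence_set"`.
#' @export
#' @examples
#' sequence_set(c(a = "acgt", b = "TTTT"))
sequence_set <- function(x) {
  if (!is.character(x) || length(x) < 1)
    stop("a sequence set needs at least one character sequence")
  ids <- names(x)
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence must have a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id(s): ", paste(unique(dup), collapse = ", "))
  x <- toupper(x)
  if (any(!nzchar(x)))
    stop("empty sequence: ", paste(ids[!nzchar(x)], collapse = ", "))
  bad <- grepl(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), x)
  if (any(bad)) {
    i <- which(bad)[1]
    ch <- regmatches(x[i], regexpr(sprintf("[^%s]", paste(IUPAC_DNA, collapse = "")), x[i]))
    stop(sprintf("sequence '%s' contains non-IUPAC character '%s'", ids[i], ch))
  }
  structure(x, class = "sequence_set")
}

#' @export
print.sequence_set <- function(x, ...) {
  cat(sprintf("sequence_set: %d sequence(s), lengths %d..%d\n",
              length(x), min(nchar(x)), max(nchar(x))))
  for (i in head(seq_along(x), 6)) {
    s <- unclass(x)[i]
    cat(sprintf("  %s  (%d bp)  %s%s\n", names(x)[i], nchar(s),
                substr(s, 1, 40), if (nchar(s) > 40) "..." else ""))
  }
  if (length(x) > 6) cat(sprintf("  ... and %d more\n", length(x) - 6))
  invisible(x)
}

as_sequence_set <- function(x) {
  if (inherits(x, "sequence_set")) x else sequence_set(x)
}

#' Read a multi-record DNA FASTA file
#'
#' Parses a FASTA file into a [sequence_set()].  The id of each record is the
#' first whitespace-delimited token of its header; the remainder is kept as
#' the description.  Sequence lines are concatenated and upper-cased.
#' Malformed input (a file not starting with `>`, an empty record, a
#' duplicate id, or a non-IUPAC residue) raises an error naming the offending
#' record and line.
#'
#' @param path path to a FASTA file.
#' @return a `sequence_set`, with record descriptions in attribute
#'   `"description"`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(nzchar(trimws(lines)))
  if (!length(nonblank)) stop("empty FASTA file: ", path)
  if (!startsWith(trimws(lines[nonblank[1]]), ">"))
    stop(sprintf("not FASTA: line %d of '%s' does not start with '>'",
                 nonblank[1], path))
  hdr <- which(startsWith(lines, ">"))
  ids <- character(0); desc <- character(0); seqs <- character(0)
  bad_re <- sprintf("[^%s]", paste(IUPAC_DNA, collapse = ""))
  for (k in seq_along(hdr)) {
    h <- hdr[k]
    header <- sub("^>", "", lines[h])
    tok <- strsplit(trimws(header), "\\s+")[[1]]
    id <- if (length(tok)) tok[1] else ""
    if (!nzchar(id))
      stop(sprintf("record at line %d has an empty id", h))
    if (id %in% ids)
      stop(sprintf("duplicate id '%s' at line %d", id, h))
    from <- h + 1
    to <- if (k < length(hdr)) hdr[k + 1] - 1 else length(lines)
    body <- if (from > to) character(0) else lines[from:to]
    body <- gsub("\\s+", "", body)
    res <- toupper(paste(body, collapse = ""))
    if (!nzchar(res))
      stop(sprintf("record '%s' (line %d) has an empty sequence", id, h))
    for (j in seq_along(body)) {
      m <- regexpr(bad_re, toupper(body[j]))
      if (m > 0)
        stop(sprintf("record '%s': non-IUPAC character '%s' at line %d",
                     id, substr(toupper(body[j]), m, m), from + j - 1))
    }
    ids <- c(ids, id)
    desc <- c(desc, trimws(sub("^\\S+\\s*", "", trimws(header))))
    seqs <- c(seqs, res)
  }
  out <- sequence_set(stats::setNames(seqs, ids))
  attr(out, "description") <- stats::setNames(desc, ids)
  out
}

#' Write a sequence set as FASTA
#'
#' @param seqs a [sequence_set()] or named character vector.
#' @param path output file.
#' @param width line width for wrapping residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70) {
  seqs <- as_sequence_set(seqs)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- unclass(seqs)[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

fmt_dist <- function(x) {
  # >= 6 significant digits; fixed notation where it stays readable
  ifelse(x == 0, "0.0000000000",
         ifelse(abs(x) >= 1e-4, sprintf("%.10f", x), sprintf("%.6e", x)))
}

#' Write a distance matrix in square PHYLIP format
#'
#' The first line holds the number of sequences; each following line holds a
#' label and the full row of distances.  By default labels are written in the
#' "relaxed" dialect (full id followed by a space), because modern accession
#' ids exceed the classic 10-character field; `strict = TRUE` pads/truncates
#' labels to exactly 10 characters.
#'
#' @param dm symmetric numeric matrix with identical row/column names.
#' @param path output file.
#' @param strict use the classic fixed 10-character label field.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path, strict = FALSE) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm), !is.null(rownames(dm)))
  labs <- rownames(dm)
  if (strict) labs <- sprintf("%-10s", substr(labs, 1, 10))
  rows <- vapply(seq_len(nrow(dm)), function(i) {
    paste(c(labs[i], fmt_dist(dm[i, ])), collapse = " ")
  }, character(1))
  writeLines(c(as.character(nrow(dm)), rows), path)
  invisible(path)
}

#' Read a square PHYLIP distance matrix (relaxed labels)
#'
#' @param path file written by [write_phylip()] or compatible.
#' @return symmetric numeric matrix with dimnames.
#' @export
read_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  n <- as.integer(trimws(lines[1]))
  toks <- strsplit(trimws(lines[1 + seq_len(n)]), "\\s+")
  labs <- vapply(toks, `[`, character(1), 1)
  m <- t(vapply(toks, function(tk) as.numeric(tk[-1]), numeric(n)))
  dimnames(m) <- list(labs, labs)
  m
}

quote_newick_label <- function(lab) {
  if (grepl("[\\s()\\[\\]{}:;,']", lab, perl = TRUE))
    paste0("'", gsub("'", "''", lab), "'")
  else lab
}

fmt_brlen <- function(x) {
  ifelse(x == 0 | abs(x) >= 1e-4, sprintf("%.6f", x), sprintf("%.6e", x))
}

#' Serialize a phylogenetic tree to Newick
#'
#' Writes an [ape::ape-package] `"phylo"` tree as a Newick string with branch
#' lengths at six significant digits and labels containing Newick
#' metacharacters single-quoted.
#'
#' @param tree an object of class `"phylo"`; every tip must be labeled.
#' @param path optional output file; if `NULL` the string is returned.
#' @return the Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, path = NULL) {
  stopifnot(inherits(tree, "phylo"))
  ntip <- length(tree$tip.label)
  if (ntip < 2) stop("tree must have at least 2 leaves")
  if (any(is.na(tree$tip.label)) || any(!nzchar(tree$tip.label)))
    stop("every leaf must be labeled")
  kids <- split(seq_len(nrow(tree$edge)), tree$edge[, 1])
  rec <- function(node) {
    rows <- kids[[as.character(node)]]
    if (is.null(rows)) return(quote_newick_label(tree$tip.label[node]))
    inner <- vapply(rows, function(r) {
      paste0(rec(tree$edge[r, 2]),
             if (!is.null(tree$edge.length))
               paste0(":", fmt_brlen(tree$edge.length[r])) else "")
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  s <- paste0(rec(ntip + 1L), ";")
  if (is.null(path)) return(s)
  writeLines(s, path)
  invisible(s)
}

#' Write an MDS embedding as TSV
#'
#' Columns: `id`, then `dim1..dimk`.
#'
#' @param emb an [classical_mds()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mds_tsv <- function(emb, path) {
  stopifnot(inherits(emb, "mds_embedding"))
  df <- data.frame(id = emb$labels, emb$points, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c("id", paste0("dim", seq_len(ncol(emb$points))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an occurrence or frequency matrix as TSV
#'
#' Header row holds the L-words in lexicographic order; the first column
#' holds the sequence ids.
#'
#' @param m matrix with sequence-id rownames and word colnames.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(m, path) {
  df <- data.frame(id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
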
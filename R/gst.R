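# R surface of the generalized suffix tree (suffixtree module).

#' Build a generalized suffix tree over a sequence set
#'
#' Constructs a compressed suffix tree containing every suffix of every
#' sequence, each terminated by its own unique sentinel symbol drawn outside
#' the IUPAC alphabet.  The full tree is built online in linear time
#' (Ukkonen); with `max_depth = k` a k-truncated tree is built instead, in
#' which every path is cut at string depth k and a truncated leaf aggregates
#' the annotations of all suffixes sharing that k-prefix.  Word queries of
#' length at most k give identical results on either structure.
#'
#' Ambiguity letters (N, R, Y, ...) are kept in the tree as ordinary symbols
#' so the suffix structure is exact, but word queries are restricted to the
#' {A,C,G,T} alphabet, so windows containing an ambiguous base are never
#' counted.
#'
#' @param seqs a [sequence_set()] or named character vector of DNA sequences.
#' @param max_depth optional truncation depth (k >= 1); `NULL` builds the
#'   full tree.
#' @return an object of class `"gst"`.
#' @export
#' @examples
#' tr <- build_gst(c(s1 = "ACGTACGT", s2 = "TTTT"))
#' count_word(tr, "CG")
build_gst <- function(seqs, max_depth = NULL) {
  seqs <- as_sequence_set(seqs)
  if (!is.null(max_depth)) {
    max_depth <- as.integer(max_depth)
    if (is.na(max_depth) || max_depth < 1) stop("max_depth must be >= 1")
  }
  ptr <- gst_build_cpp(unclass(seqs), if (is.null(max_depth)) 0L else max_depth)
  structure(list(ptr = ptr,
                 labels = names(seqs),
                 lengths = nchar(seqs),
                 n = length(seqs),
                 max_depth = max_depth),
            class = "gst")
}

#' @export
print.gst <- function(x, ...) {
  st <- gst_stats(x)
  cat(sprintf("generalized suffix tree: %d sequence(s), %d bases%s\n",
              x$n, sum(x$lengths),
              if (is.null(x$max_depth)) ""
              else sprintf(", truncated at depth %d", x$max_depth)))
  cat(sprintf("  %d nodes (%d leaves), %.0f leaf annotations\n",
              st$n_nodes, st$n_leaves, st$n_annotations))
  invisible(x)
}

#' Suffix tree size statistics
#'
#' @param tree a [build_gst()] result.
#' @return list with node, leaf and annotation counts and total text length
#'   (residues plus one sentinel per sequence).
#' @export
gst_stats <- function(tree) {
  stopifnot(inherits(tree, "gst"))
  gst_stats_cpp(tree$ptr)
}

#' Count occurrences of one word in every sequence
#'
#' Traverses the tree once from the root along the path labeled `w`; the leaf
#' annotations below the reached point give the number of (possibly
#' overlapping) occurrences of `w` in each sequence.  If the traversal falls
#' off the tree the word occurs nowhere and an all-zero vector is returned.
#'
#' @param tree a [build_gst()] result.
#' @param w a non-empty word over {A,C,G,T}.
#' @return integer vector of per-sequence counts, named by sequence id.
#' @export
count_word <- function(tree, w) {
  stopifnot(inherits(tree, "gst"))
  if (!is.character(w) || length(w) != 1 || !nzchar(w))
    stop("w must be a single non-empty word")
  w <- toupper(w)
  if (grepl("[^ACGT]", w))
    stop("query word must be over {A,C,G,T}: ", w)
  if (!is.null(tree$max_depth) && nchar(w) > tree$max_depth)
    stop(sprintf("word length %d exceeds tree truncation depth %d",
                 nchar(w), tree$max_depth))
  stats::setNames(gst_count_word_cpp(tree$ptr, w), tree$labels)
}

#' Count every occurring word of one length in a single traversal
#'
#' One depth-bounded depth-first traversal collects, at string depth exactly
#' `L` (possibly mid-edge), the aggregated leaf annotations.  Paths crossing
#' a sentinel or an ambiguity symbol are skipped, so only pure-ACGT words are
#' reported.  Equivalent to calling [count_word()] for each of the 4^L words
#' and dropping the all-zero ones.
#'
#' @param tree a [build_gst()] result.
#' @param L word length (>= 1; at most the truncation depth, if truncated).
#' @return named list mapping each occurring L-word (lexicographic order) to
#'   its integer per-sequence count vector.
#' @export
count_all_words_at_depth <- function(tree, L) {
  stopifnot(inherits(tree, "gst"))
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be >= 1")
  if (!is.null(tree$max_depth) && L > tree$max_depth)
    stop(sprintf("L = %d exceeds tree truncation depth %d", L, tree$max_depth))
  res <- gst_words_at_depth_cpp(tree$ptr, L)
  counts <- res$counts
  rownames(counts) <- tree$labels
  out <- lapply(seq_along(res$words), function(j)
    stats::setNames(counts[, j], tree$labels))
  names(out) <- res$words
  out
}

# Internal: one row per leaf annotation with the spelled root-to-leaf path
# (sentinel rendered as '$'); used to test the structural invariants.
gst_annotations <- function(tree) {
  stopifnot(inherits(tree, "gst"))
  gst_annotations_cpp(tree$ptr)
}

# Internal: structural audit (path compression, distinct child symbols).
gst_validate <- function(tree) {
  stopifnot(inherits(tree, "gst"))
  gst_check_cpp(tree$ptr)
}
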
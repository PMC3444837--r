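# Word-length selection, word enumeration, occurrence and frequency
# profiles, and the independent sliding-window counting oracle.

WORD_LENGTH_GUARD <- 12L

#' Select the word length from the sequence lengths
#'
#' The word length L is the lower limit of the optimal resolution range for
#' word-composition comparison: with m the length of the longest sequence,
#' L = ceiling(log4(m)), computed in exact integer arithmetic as the smallest
#' L with 4^L >= m (and at least 1).
#'
#' @param seqs a [sequence_set()] or named character vector.
#' @return list with components `m` (longest sequence length), `L` (word
#'   length) and `t` (number of possible L-words, 4^L), classed
#'   `"word_length_selection"`.
#' @export
#' @examples
#' select_word_length(c(s = strrep("A", 17036)))  # L = 8
select_word_length <- function(seqs) {
  seqs <- as_sequence_set(seqs)
  m <- max(nchar(seqs))
  L <- 1L
  while (4^L < m) L <- L + 1L
  if (L > WORD_LENGTH_GUARD)
    stop(sprintf("selected word length %d exceeds the guard (%d)",
                 L, WORD_LENGTH_GUARD))
  structure(list(m = m, L = L, t = 4^L), class = "word_length_selection")
}

#' @export
print.word_length_selection <- function(x, ...) {
  cat(sprintf("word length selection: m = %d, L = %d, t = 4^%d = %d\n",
              x$m, x$L, x$L, x$t))
  invisible(x)
}

#' Enumerate all words of a given length
#'
#' All 4^L words over {A,C,G,T} in lexicographic order (A < C < G < T), e.g.
#' for L = 2: AA, AC, AG, AT, CA, ..., TT.
#'
#' @param L word length, 1..12 (the upper guard protects memory: 4^13 words
#'   would not fit comfortably).
#' @return character vector of length 4^L.
#' @export
enumerate_words <- function(L) {
  L <- as.integer(L)
  if (is.na(L) || L < 1) stop("L must be >= 1")
  if (L > WORD_LENGTH_GUARD)
    stop(sprintf("L = %d exceeds the guard (%d)", L, WORD_LENGTH_GUARD))
  w <- c("A", "C", "G", "T")
  if (L == 1) return(w)
  out <- w
  for (i in 2:L) out <- paste0(rep(out, each = 4), w)
  out
}

#' Occurrence matrix of all L-words in all sequences
#'
#' The n x 4^L matrix O with O[i, j] the number of (overlapping) occurrences
#' of word j in sequence i, rows in input order and columns the full
#' lexicographic word list (absent words are zero columns).  Counts come from
#' a single depth-L traversal of the suffix tree; for a sequence with no
#' ambiguity codes the row sums to m_i - L + 1.
#'
#' @param tree a [build_gst()] result over exactly these sequences.
#' @param seqs the same sequence set the tree was built from.
#' @param sel a [select_word_length()] result, or a bare integer L.
#' @return integer matrix with sequence-id rownames and word colnames.
#' @export
occurrence_matrix <- function(tree, seqs, sel) {
  seqs <- as_sequence_set(seqs)
  stopifnot(inherits(tree, "gst"))
  if (!identical(tree$labels, names(seqs)))
    stop("tree was not built over these sequences (labels differ)")
  L <- if (inherits(sel, "word_length_selection")) sel$L else as.integer(sel)
  short <- nchar(seqs) < L
  if (any(short))
    stop(sprintf("sequence '%s' is shorter than L = %d: cannot form any L-word",
                 names(seqs)[which(short)[1]], L))
  words <- enumerate_words(L)
  O <- matrix(0L, nrow = length(seqs), ncol = length(words),
              dimnames = list(names(seqs), words))
  hits <- count_all_words_at_depth(tree, L)
  if (length(hits))
    O[, names(hits)] <- vapply(hits, identity, integer(length(seqs)))
  O
}

#' Relative-frequency matrix from an occurrence matrix
#'
#' Each row of O is divided by its sum, giving per-sequence relative
#' frequencies that sum to one.
#'
#' @param O an [occurrence_matrix()] result (every row sum must be positive).
#' @return numeric matrix of the same shape.
#' @export
frequency_matrix <- function(O) {
  stopifnot(is.matrix(O))
  rs <- rowSums(O)
  if (any(rs == 0))
    stop(sprintf("sequence '%s' contributed no valid L-words (all-zero row)",
                 rownames(O)[which(rs == 0)[1]]))
  O / rs
}

#' Sliding-window word counts (independent oracle)
#'
#' Counts L-words in one sequence by scanning every window of length L,
#' shifting one base at a time (m - L + 1 windows).  Windows containing a
#' non-ACGT symbol are skipped.  This routine never touches the suffix tree;
#' it exists as an independent reference for testing the tree-based counts.
#'
#' @param seq a single DNA sequence (character scalar).
#' @param L word length.
#' @return named integer vector over the full lexicographic word list; all
#'   zeros when the sequence is shorter than L.
#' @export
oracle_counts <- function(seq, L) {
  stopifnot(is.character(seq), length(seq) == 1)
  seq <- toupper(seq)
  L <- as.integer(L)
  words <- enumerate_words(L)
  m <- nchar(seq)
  if (m < L)
    return(stats::setNames(integer(length(words)), words))
  starts <- seq_len(m - L + 1)
  win <- substring(seq, starts, starts + L - 1)
  win <- win[grepl("^[ACGT]+$", win)]
  tab <- table(factor(win, levels = words))
  stats::setNames(as.integer(tab), words)
}
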
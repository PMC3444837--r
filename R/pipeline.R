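# End-to-end comparison: the central classed result and the file-based
# pipeline that backs the command-line script.

#' Alignment-free comparison of a DNA sequence set
#'
#' Runs the whole word-frequency comparison in memory: selects the word
#' length L from the longest sequence (unless overridden), builds the
#' generalized suffix tree (optionally truncated at depth L), counts all
#' L-words per sequence, normalizes to relative-frequency profiles and
#' computes the pairwise standard Euclidean distance matrix.
#'
#' @param seqs a [sequence_set()], named character vector, or path to a
#'   FASTA file.
#' @param word_length optional word-length override (1..12); by default
#'   L = ceiling(log4(m)) with m the longest sequence length.
#' @param truncated build a depth-truncated suffix tree (depth L) instead of
#'   the full tree; results are identical, memory is smaller.
#' @return an object of class `"lword_compare"` with components `selection`
#'   (m, L, t), `occurrence`, `frequency` (n x 4^L matrices), `distance`
#'   (n x n symmetric matrix), `ids`, `lengths`, `truncated` and `call`.
#' @seealso [neighbor_joining()], [classical_mds()], [run_pipeline()]
#' @export
#' @examples
#' seqs <- random_sequences(4, 600, seed = 42)
#' fit <- lword_compare(seqs)
#' fit
#' nj <- neighbor_joining(fit$distance)
lword_compare <- function(seqs, word_length = NULL, truncated = FALSE) {
  cl <- match.call()
  if (is.character(seqs) && length(seqs) == 1 && is.null(names(seqs)) &&
      file.exists(seqs))
    seqs <- read_fasta(seqs)
  seqs <- as_sequence_set(seqs)
  sel <- select_word_length(seqs)
  if (!is.null(word_length)) {
    L <- as.integer(word_length)
    if (is.na(L) || L < 1 || L > WORD_LENGTH_GUARD)
      stop(sprintf("word_length must be in 1..%d", WORD_LENGTH_GUARD))
    sel$L <- L
    sel$t <- 4^L
  }
  tree <- build_gst(seqs, max_depth = if (truncated) sel$L else NULL)
  O <- occurrence_matrix(tree, seqs, sel)
  Fm <- frequency_matrix(O)
  D <- sed_matrix(Fm)
  structure(list(ids = names(seqs), lengths = unname(nchar(seqs)),
                 selection = sel, occurrence = O, frequency = Fm,
                 distance = D, truncated = isTRUE(truncated), call = cl),
            class = "lword_compare")
}

#' @export
print.lword_compare <- function(x, ...) {
  cat("Alignment-free L-word comparison\n")
  cat(sprintf("  sequences : %d (lengths %d..%d)\n", length(x$ids),
              min(x$lengths), max(x$lengths)))
  cat(sprintf("  word length L = %d (m = %d, t = 4^%d = %d)%s\n",
              x$selection$L, x$selection$m, x$selection$L, x$selection$t,
              if (x$truncated) ", truncated tree" else ""))
  cat(sprintf("  SED range : %.6f .. %.6f\n",
              min(x$distance[upper.tri(x$distance)]),
              max(x$distance[upper.tri(x$distance)])))
  invisible(x)
}

#' @export
summary.lword_compare <- function(object, ...) {
  print(object)
  ut <- object$distance[upper.tri(object$distance)]
  cat(sprintf("  mean SED  : %.6f\n", mean(ut)))
  occ <- colSums(object$occurrence) > 0
  cat(sprintf("  words seen: %d of %d possible\n", sum(occ), length(occ)))
  invisible(object)
}

#' Plot method: classical MDS map of the sequences
#'
#' @param x an [lword_compare()] result.
#' @param k embedding dimension for MDS (the first two are plotted).
#' @param ... passed to [graphics::plot()].
#' @export
plot.lword_compare <- function(x, k = 2, ...) {
  emb <- classical_mds(x$distance, k = max(2, k))
  plot(emb$points[, 1], emb$points[, 2], xlab = "MDS 1", ylab = "MDS 2",
       pch = 19, ...)
  text(emb$points[, 1], emb$points[, 2], labels = x$ids, pos = 3, cex = 0.8)
  invisible(emb)
}

#' Run the full FASTA-to-files pipeline
#'
#' Reads a FASTA file, runs [lword_compare()], and writes the requested
#' outputs next to `out_prefix`: `<prefix>.freq.tsv` (frequency profiles),
#' `<prefix>.dist.phylip` (PHYLIP square distance matrix),
#' `<prefix>.nj.nwk` (neighbor-joining tree) and `<prefix>.mds.tsv`
#' (MDS coordinates).  Progress (n, m, L, t, timings) is logged to stderr;
#' on failure no partial outputs are left behind.
#'
#' @param input path to a FASTA file.
#' @param out_prefix prefix for output files.
#' @param outputs subset of `c("freq", "dist", "nj", "mds")`.
#' @param word_length optional word-length override.
#' @param truncated build a depth-truncated suffix tree.
#' @param mds_dims MDS embedding dimension.
#' @param strict_phylip write classic 10-character PHYLIP labels.
#' @param quiet suppress the stderr log.
#' @return named character vector of the files written, invisibly.
#' @export
run_pipeline <- function(input, out_prefix,
                         outputs = c("freq", "dist", "nj"),
                         word_length = NULL, truncated = FALSE,
                         mds_dims = 2, strict_phylip = FALSE,
                         quiet = FALSE) {
  outputs <- match.arg(outputs, c("freq", "dist", "nj", "mds"),
                       several.ok = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]
  seqs <- read_fasta(input)
  fit <- lword_compare(seqs, word_length = word_length, truncated = truncated)
  say("n = %d sequences, m = %d, L = %d, t = %d%s",
      length(fit$ids), fit$selection$m, fit$selection$L, fit$selection$t,
      if (truncated) " (truncated tree)" else "")

  written <- character(0)
  on.exit(if (length(written)) unlink(written))
  if ("freq" %in% outputs) {
    f <- paste0(out_prefix, ".freq.tsv")
    write_profile_tsv(fit$frequency, f)
    written <- c(written, freq = f)
  }
  if ("dist" %in% outputs) {
    f <- paste0(out_prefix, ".dist.phylip")
    write_phylip(fit$distance, f, strict = strict_phylip)
    written <- c(written, dist = f)
  }
  if ("nj" %in% outputs) {
    f <- paste0(out_prefix, ".nj.nwk")
    write_newick(neighbor_joining(fit$distance), f)
    written <- c(written, nj = f)
  }
  if ("mds" %in% outputs) {
    f <- paste0(out_prefix, ".mds.tsv")
    write_mds_tsv(classical_mds(fit$distance, k = mds_dims), f)
    written <- c(written, mds = f)
  }
  on.exit()
  say("wrote %s in %.2f s", paste(basename(written), collapse = ", "),
      proc.time()[["elapsed"]] - t0)
  invisible(written)
}
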
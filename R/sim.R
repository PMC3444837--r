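# Synthetic-data generator: random DNA and sequences evolved down a known
# tree, so every pipeline stage is testable without external downloads.

with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)
  force(code)
}

#' Generate random DNA sequences
#'
#' Bases are drawn i.i.d. uniformly from {A,C,G,T}; output is deterministic
#' for a fixed seed.
#'
#' @param n number of sequences (>= 1).
#' @param length length of each sequence in bases (>= 1).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param ids optional sequence ids (default `seq1..seqn`).
#' @return a [sequence_set()].
#' @export
random_sequences <- function(n, length, seed = NULL, ids = NULL) {
  stopifnot(n >= 1, length >= 1)
  if (is.null(ids)) ids <- paste0("seq", seq_len(n))
  with_seed(seed, {
    seqs <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
            collapse = ""), character(1))
    sequence_set(stats::setNames(seqs, ids))
  })
}

mutate_codes <- function(codes, prob) {
  hit <- which(runif(length(codes)) < prob)
  if (length(hit))
    codes[hit] <- (codes[hit] + sample.int(3, length(hit), replace = TRUE) - 1L) %% 4L + 1L
  codes
}

#' Evolve sequences down a tree by per-branch substitution
#'
#' A root sequence is drawn uniformly at random; along each branch each site
#' independently substitutes, with probability `sub_prob`, to a uniformly
#' chosen different base (a Jukes-Cantor-like model with one mutation round
#' per branch and no indels).  Leaf sequences are returned in the tree's tip
#' order together with the true tree.
#'
#' @param tree a `"phylo"` tree, or `NULL` to draw a random topology with
#'   `n_taxa` tips (via [ape::rtree()]).
#' @param n_taxa number of taxa when `tree` is `NULL`.
#' @param root_length root sequence length in bases.
#' @param sub_prob per-branch per-site substitution probability in [0, 1].
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return list with `sequences` (a [sequence_set()] named by tip labels) and
#'   `tree` (the true `"phylo"` tree).
#' @export
evolve_on_tree <- function(tree = NULL, n_taxa = 6, root_length = 1000,
                           sub_prob = 0.02, seed = NULL) {
  stopifnot(root_length >= 1, sub_prob >= 0, sub_prob <= 1)
  with_seed(seed, {
    if (is.null(tree)) tree <- ape::rtree(n_taxa)
    stopifnot(inherits(tree, "phylo"))
    ntip <- length(tree$tip.label)
    tree2 <- stats::reorder(tree, "cladewise")   # parents before children
    root <- ntip + 1L
    seqs <- vector("list", ntip + tree2$Nnode)
    seqs[[root]] <- sample.int(4L, root_length, replace = TRUE)
    for (e in seq_len(nrow(tree2$edge))) {
      par <- tree2$edge[e, 1]; chd <- tree2$edge[e, 2]
      seqs[[chd]] <- mutate_codes(seqs[[par]], sub_prob)
    }
    bases <- c("A", "C", "G", "T")
    leaf <- vapply(seq_len(ntip), function(i)
      paste(bases[seqs[[i]]], collapse = ""), character(1))
    list(sequences = sequence_set(stats::setNames(leaf, tree$tip.label)),
         tree = tree)
  })
}
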
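# Downstream outputs from the distance matrix: a neighbor-joining tree and
# a classical multidimensional-scaling embedding.

#' Neighbor-joining tree from a distance matrix
#'
#' Standard agglomerative neighbor joining (Saitou & Nei): repeatedly join
#' the pair (i, j) minimizing Q(i, j) = (r - 2) d(i, j) - R_i - R_j, where r
#' is the number of active clusters and R the row sums; pendant branch
#' lengths follow the usual two-point formulas and the joined pair is
#' replaced by a node at distance (d(i,k) + d(j,k) - d(i,j)) / 2 from every
#' other cluster k.  Conventions fixed here for determinism:
#' \itemize{
#'   \item ties in Q are broken by the lexicographically smallest (row,
#'     column) index pair in the current cluster ordering;
#'   \item a negative estimated branch length is clamped to zero and the
#'     deficit transferred to its sister branch (their sum is preserved);
#'   \item n = 2 yields a single edge split evenly between the two leaves.
#' }
#' The returned tree is unrooted (for n >= 3 the basal node is a
#' trifurcation); any rooting for display is the consumer's choice.
#'
#' @param dm symmetric distance matrix with labels as dimnames (n >= 2).
#' @return an unrooted tree of class `"phylo"` (ape).
#' @export
neighbor_joining <- function(dm) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  if (n < 2) stop("need at least two taxa")
  labs <- rownames(dm)
  if (is.null(labs)) labs <- paste0("t", seq_len(n))
  if (max(abs(dm - t(dm))) > 1e-8) stop("distance matrix must be symmetric")

  fmt <- function(x) sprintf("%.17g", x)
  clamp_pair <- function(li, lj) {
    # clamp negatives to 0, transferring the deficit to the sister branch
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- max(0, li + lj); lj <- 0 }
    c(li, lj)
  }

  sub <- paste0("x", seq_len(n))   # newick fragment per active cluster
  D <- dm
  active <- seq_len(n)             # positions index rows of D
  while (length(active) > 3) {
    r <- length(active)
    A <- D[active, active, drop = FALSE]
    R <- rowSums(A)
    best <- c(NA, NA); bestq <- Inf
    for (i in seq_len(r - 1)) {
      for (j in (i + 1):r) {
        q <- (r - 2) * A[i, j] - R[i] - R[j]
        if (q + 1e-13 * max(1, abs(q)) < bestq) {
          bestq <- q; best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    dij <- A[i, j]
    li <- dij / 2 + (R[i] - R[j]) / (2 * (r - 2))
    lj <- dij - li
    ll <- clamp_pair(li, lj)
    ai <- active[i]; aj <- active[j]
    newfrag <- paste0("(", sub[ai], ":", fmt(ll[1]), ",",
                      sub[aj], ":", fmt(ll[2]), ")")
    # distances from the new node to the remaining clusters
    rest <- active[-c(i, j)]
    dnew <- (D[ai, rest] + D[aj, rest] - dij) / 2
    D <- rbind(cbind(D, 0), 0)
    u <- nrow(D)
    D[u, rest] <- dnew
    D[rest, u] <- dnew
    sub <- c(sub, newfrag)
    active <- c(rest, u)
  }

  if (length(active) == 2) {
    a <- active[1]; b <- active[2]
    h <- D[a, b] / 2
    nwk <- paste0("(", sub[a], ":", fmt(h), ",", sub[b], ":", fmt(h), ");")
  } else {
    a <- active[1]; b <- active[2]; c3 <- active[3]
    la <- max(0, (D[a, b] + D[a, c3] - D[b, c3]) / 2)
    lb <- max(0, (D[a, b] + D[b, c3] - D[a, c3]) / 2)
    lc <- max(0, (D[a, c3] + D[b, c3] - D[a, b]) / 2)
    nwk <- paste0("(", sub[a], ":", fmt(la), ",", sub[b], ":", fmt(lb), ",",
                  sub[c3], ":", fmt(lc), ");")
  }
  tree <- ape::read.tree(text = nwk)
  tree$tip.label <- labs[as.integer(sub("^x", "", tree$tip.label))]
  tree
}

#' Classical (Torgerson) multidimensional scaling of a distance matrix
#'
#' Double-centers -D^2/2, eigendecomposes, and retains the top k
#' non-negative eigenvalues; coordinates are the eigenvectors scaled by the
#' square roots of their eigenvalues.  Negative eigenvalues (the distance
#' matrix not being exactly Euclidean-embeddable in k dimensions) are zeroed
#' with a warning.
#'
#' @param dm symmetric distance matrix with labels as dimnames.
#' @param k number of embedding dimensions (default 2; must be < n).
#' @return list with `labels`, `points` (n x k coordinate matrix) and `eig`
#'   (the k retained eigenvalues, descending), classed `"mds_embedding"`.
#' @export
classical_mds <- function(dm, k = 2) {
  stopifnot(is.matrix(dm), nrow(dm) == ncol(dm))
  n <- nrow(dm)
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be a positive integer")
  if (k >= n) stop(sprintf("k = %d must be smaller than n = %d", k, n))
  fit <- stats::cmdscale(dm, k = k, eig = TRUE)
  eig <- fit$eig[seq_len(k)]
  if (any(eig < -sqrt(.Machine$double.eps) * max(abs(fit$eig), 1)))
    warning("negative eigenvalues among the retained dimensions; zeroed")
  eig <- pmax(eig, 0)
  pts <- matrix(0, n, k, dimnames = list(rownames(dm), NULL))
  got <- ncol(fit$points)
  if (got > 0) pts[, seq_len(min(k, got))] <- fit$points[, seq_len(min(k, got))]
  structure(list(labels = rownames(dm), points = pts, eig = eig),
            class = "mds_embedding")
}

#' @export
print.mds_embedding <- function(x, ...) {
  cat(sprintf("classical MDS embedding: %d points in %d dimension(s)\n",
              nrow(x$points), ncol(x$points)))
  cat("eigenvalues:", format(x$eig, digits = 6), "\n")
  invisible(x)
}
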
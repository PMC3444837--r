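# Pairwise standard Euclidean distance over L-word frequency profiles.

#' Standard Euclidean distance matrix between frequency profiles
#'
#' For sequences X and Y with relative-frequency profiles f_X and f_Y over
#' the L-word list, SED(X, Y) = sqrt(sum_w (f_Xw - f_Yw)^2).  Only the upper
#' triangle is computed and then mirrored, so the result is exactly
#' symmetric with a zero diagonal.  For profiles that each sum to one the
#' sharp upper bound is sqrt(2); values are reported as computed, never
#' clipped or rescaled.
#'
#' @param F a [frequency_matrix()] result (n >= 2 rows).
#' @return symmetric n x n numeric matrix with sequence-id dimnames.
#' @export
sed_matrix <- function(F) {
  stopifnot(is.matrix(F))
  n <- nrow(F)
  if (n < 2) stop("need at least two sequences")
  D <- matrix(0, n, n, dimnames = list(rownames(F), rownames(F)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d <- sqrt(sum((F[i, ] - F[j, ])^2))
      D[i, j] <- d
      D[j, i] <- d
    }
  }
  D
}
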
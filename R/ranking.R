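#' Rank-transform an expression matrix
#'
#' Replaces each gene's expression profile by its sample ranks (0-based), the
#' copula-space input of the adaptive-partitioning MI estimator.  Every row
#' of the result is a strict permutation of `0:(M-1)`: ties are broken
#' uniformly at random using an RNG stream derived deterministically from
#' `(seed, gene row index)`, so the same matrix and seed always give the same
#' ranks, independently of the caller's RNG state and of the order in which
#' genes are ranked.
#'
#' Because only ranks are passed downstream, all MI estimates are invariant
#' to strictly increasing per-gene transforms of the raw values (log scaling,
#' library-size factors, and so on).
#'
#' @param matrix Numeric expression matrix (genes x samples) with dimnames.
#' @param seed Integer seed for tie-breaking.
#' @return Integer matrix of the same shape and dimnames; each row a
#'   permutation of `0:(ncol(matrix)-1)`.
#' @examples
#' m <- matrix(c(5, 1, 3, 2, 2, 4), nrow = 2, byrow = TRUE,
#'             dimnames = list(c("g1", "g2"), c("s1", "s2", "s3")))
#' rank_transform(m, seed = 1)
#' @export
rank_transform <- function(matrix, seed = 0L) {
  validate_expression(matrix)
  ranks <- matrix(0L, nrow = nrow(matrix), ncol = ncol(matrix),
                  dimnames = dimnames(matrix))
  for (g in seq_len(nrow(matrix))) {
    ranks[g, ] <- with_seed(
      derive_seed(seed, 1L, g),
      rank(matrix[g, ], ties.method = "random")) - 1L
  }
  ranks
}
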
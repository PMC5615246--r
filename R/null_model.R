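#' Permute an expression matrix row-wise
#'
#' Independently shuffles each gene's values across samples, destroying all
#' gene-gene dependence while preserving every marginal — the permutation
#' null of the ARACNE family.  Reproducible: each row uses an RNG stream
#' derived from `(seed, row index)`.
#'
#' @param matrix Numeric expression matrix with dimnames.
#' @param seed Integer seed.
#' @return Matrix of the same shape and dimnames with rows shuffled.
#' @export
permute_matrix <- function(matrix, seed = 0L) {
  validate_expression(matrix)
  m <- ncol(matrix)
  out <- matrix
  for (g in seq_len(nrow(matrix))) {
    perm <- with_seed(derive_seed(seed, 2L, g), sample.int(m))
    out[g, ] <- matrix[g, perm]
  }
  out
}

#' Sample the permutation null distribution of MI
#'
#' Builds the baseline MI distribution used for thresholding: the matrix is
#' permuted row-wise, rank-transformed, and `n0` (TF, gene) pairs (TF !=
#' gene, drawn uniformly with replacement) are scored with the apMI
#' estimator.  The sorted values form an empirical distribution; in
#' addition, a right-tail survival model is fitted — a least-squares line of
#' `log(empirical survival)` against MI over the largest `ceiling(n0/1000)`
#' (at least 50) distinct upper-tail values — so that thresholds beyond the
#' empirical range (p below `1/n0`) can be extrapolated.
#'
#' @param matrix Numeric expression matrix.
#' @param tfs TF row indices.
#' @param n0 Number of null MI values (default 100000, minimum 100).
#' @param seed Integer seed.
#' @param chi2_crit,min_points Estimator parameters, as in [apmi_pair()].
#' @return Object of class `null_mi_distribution`: list with sorted
#'   `mi_values`, `n0`, and `tail_fit` (named vector `slope`, `intercept`).
#' @seealso [mi_threshold()]
#' @export
sample_null_mis <- function(matrix, tfs, n0 = 100000L, seed = 0L,
                            chi2_crit = 7.815, min_points = 8L) {
  validate_expression(matrix, min_samples = 8L)
  tfs <- validate_tf_indices(tfs, matrix)
  n0 <- as.integer(n0)
  if (is.na(n0) || n0 < 100L)
    stop("n0 must be at least 100 (the tail fit is undefined below that)")

  permuted <- permute_matrix(matrix, derive_seed(seed, 3L, 0L))
  ranks <- rank_transform(permuted, derive_seed(seed, 3L, 1L))

  n_genes <- nrow(matrix)
  pairs <- with_seed(derive_seed(seed, 3L, 2L), {
    tf_draw <- tfs[sample.int(length(tfs), n0, replace = TRUE)]
    gene_draw <- sample.int(n_genes, n0, replace = TRUE)
    while (any(self <- tf_draw == gene_draw)) {
      gene_draw[self] <- sample.int(n_genes, sum(self), replace = TRUE)
    }
    list(tf = tf_draw, gene = gene_draw)
  })

  mis <- .apmi_batch_cpp(ranks, pairs$tf, pairs$gene, chi2_crit,
                         as.integer(min_points))
  mis <- sort(mis)

  structure(
    list(mi_values = mis, n0 = n0, tail_fit = fit_null_tail(mis, n0)),
    class = "null_mi_distribution")
}

# Least-squares line of log(survival) vs MI over the distinct upper-tail
# values; the exponential-tail model behind sub-1/n0 extrapolation.
fit_null_tail <- function(sorted_mis, n0) {
  k <- max(ceiling(n0 / 1000), 50L)
  distinct <- unique(sorted_mis)          # ascending
  tail_vals <- utils::tail(distinct, k)
  # survival (# >= t)/n0 via position of the first occurrence of t
  first_at <- match(tail_vals, sorted_mis)
  surv <- (n0 - first_at + 1L) / n0
  keep <- tail_vals > 0
  if (sum(keep) < 2L) return(c(slope = NA_real_, intercept = NA_real_))
  fit <- lm(log(surv[keep]) ~ tail_vals[keep])
  c(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]))
}

#' @export
print.null_mi_distribution <- function(x, ...) {
  cat(sprintf(
    "null_mi_distribution: n0 = %d, median = %.4g, max = %.4g, tail slope = %.4g\n",
    x$n0, stats::median(x$mi_values), max(x$mi_values), x$tail_fit[["slope"]]))
  invisible(x)
}

#' MI threshold at a given p-value from the permutation null
#'
#' For `p_value >= 1/n0` the threshold is the empirical upper quantile: the
#' smallest observed null MI `t` with `(# null MIs >= t)/n0 <= p_value`.
#' Below the empirical resolution (`p_value < 1/n0`, e.g. p = 1e-8 against
#' the default 1e5 null values) the threshold is extrapolated from the
#' fitted exponential right tail, `(log(p) - intercept)/slope`, floored at
#' the empirical maximum.  The threshold is non-increasing in `p_value`.
#'
#' @param null A `null_mi_distribution` from [sample_null_mis()].
#' @param p_value Significance level in (0, 1].
#' @return MI threshold in nats.
#' @export
mi_threshold <- function(null, p_value) {
  if (!inherits(null, "null_mi_distribution"))
    stop("null must be a null_mi_distribution")
  if (!is.numeric(p_value) || length(p_value) != 1L || is.na(p_value) ||
      p_value <= 0 || p_value > 1)
    stop("p_value must be in (0, 1]")

  v <- null$mi_values
  n0 <- null$n0
  if (p_value >= 1 / n0) {
    distinct <- unique(v)                 # ascending
    surv <- (n0 - match(distinct, v) + 1L) / n0
    ok <- which(surv <= p_value)
    if (length(ok)) return(distinct[ok[1L]])
    # p below the survival of the (tied) maximum: fall through to the tail
  }
  slope <- null$tail_fit[["slope"]]
  intercept <- null$tail_fit[["intercept"]]
  if (!is.finite(slope) || slope >= 0)
    stop("the null distribution has too few distinct positive MI values to ",
         "resolve p = ", format(p_value), "; use a larger p-value, a larger ",
         "n0, or more genes (the null spans one value per distinct TF-gene ",
         "pair)")
  max((log(p_value) - intercept) / slope, max(v))
}
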
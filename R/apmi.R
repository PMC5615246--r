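#' Adaptive-partitioning mutual information for one rank pair
#'
#' Estimates the mutual information (in nats) between two variables given as
#' strict rank permutations, by adaptively quartering the 2-D rank plane.
#' A FIFO queue of rectangles is processed breadth-first: a rectangle with
#' `n` points and both rank widths at least 2 is split at the integer
#' midpoints of its intervals whenever `n >= min_points` and the chi-square
#' statistic of its four quadrant counts against local uniformity exceeds
#' `chi2_crit`; otherwise it is a leaf.  A leaf covering `n > 0` points in a
#' `w_x` by `w_y` rectangle contributes `(n/M) * log(n * M / (w_x * w_y))`,
#' the plug-in term for uniform rank marginals.  The total is clamped at
#' zero.
#'
#' The breadth-first queue is an implementation of the same partition tree a
#' plain recursion would build (see [apmi_pair_recursive()]); the two agree
#' to floating-point accumulation order.  The queue occupancy never exceeds
#' `M - 3`, reported in `max_queue_length` as a diagnostic.
#'
#' @param x_ranks,y_ranks Integer vectors, each a permutation of
#'   `0:(M-1)` (rows of [rank_transform()]).
#' @param chi2_crit Chi-square splitting threshold; the default 7.815 is the
#'   0.95 quantile at 3 degrees of freedom.
#' @param min_points Smallest rectangle occupancy eligible for splitting
#'   (default 8).
#' @return List with `mi` (nats, `>= 0`) and `max_queue_length`.
#' @examples
#' r <- 0:7
#' apmi_pair(r, r)$mi  # log(2): one split, two occupied quadrants
#' @export
apmi_pair <- function(x_ranks, y_ranks, chi2_crit = 7.815, min_points = 8L) {
  x <- as.integer(x_ranks)
  y <- as.integer(y_ranks)
  check_rank_pair(x, y)
  .apmi_pair_cpp(x, y, as.numeric(chi2_crit), as.integer(min_points))
}

#' Recursive reference implementation of the apMI estimator
#'
#' Depth-first recursive form of the estimator in [apmi_pair()], written in
#' plain R with no shared code.  It exists as an independent cross-check of
#' the queue-based kernel: the two must agree on every input up to
#' floating-point accumulation order.
#'
#' @inheritParams apmi_pair
#' @return Mutual information in nats (`>= 0`).
#' @export
apmi_pair_recursive <- function(x_ranks, y_ranks, chi2_crit = 7.815,
                                min_points = 8L) {
  x <- as.integer(x_ranks)
  y <- as.integer(y_ranks)
  check_rank_pair(x, y)
  m <- length(x)
  rec <- function(xlo, xhi, ylo, yhi, idx) {
    n <- length(idx)
    wx <- xhi - xlo
    wy <- yhi - ylo
    if (n >= min_points && wx >= 2L && wy >= 2L) {
      xm <- (xlo + xhi) %/% 2L
      ym <- (ylo + yhi) %/% 2L
      left <- x[idx] < xm
      low <- y[idx] < ym
      q <- list(idx[left & low], idx[!left & low],
                idx[left & !low], idx[!left & !low])
      e <- n / 4
      t_stat <- sum((lengths(q) - e)^2 / e)
      if (t_stat > chi2_crit) {
        return(rec(xlo, xm, ylo, ym, q[[1L]]) +
               rec(xm, xhi, ylo, ym, q[[2L]]) +
               rec(xlo, xm, ym, yhi, q[[3L]]) +
               rec(xm, xhi, ym, yhi, q[[4L]]))
      }
    }
    if (n == 0L) return(0)
    (n / m) * log(n * m / (wx * wy))
  }
  max(0, rec(0L, m, 0L, m, seq_len(m)))
}

check_rank_pair <- function(x, y) {
  m <- length(x)
  if (length(y) != m) stop("rank vectors differ in length")
  if (m < 2L) stop("need at least 2 samples")
  ref <- 0:(m - 1L)
  if (!identical(sort(x), ref) || !identical(sort(y), ref))
    stop("inputs must be strict permutations of 0..M-1")
  invisible(TRUE)
}

#' Candidate MI matrix over all TF-gene pairs
#'
#' Computes [apmi_pair()] for every (TF, gene) pair with TF != gene and
#' returns a candidate network: an `N_tf x N_genes` MI matrix plus a Boolean
#' edge mask (initially true wherever an MI is present).  Self entries are
#' absent (`NA`, mask false): self-interactions are ignored throughout.
#' Each unordered TF-TF pair is computed once and mirrored, so the matrix is
#' exactly symmetric on TF-TF entries.
#'
#' @param ranks Rank matrix from [rank_transform()].
#' @param tfs Integer vector of TF row indices (see [read_tf_list()]).
#' @param chi2_crit,min_points Estimator parameters, as in [apmi_pair()].
#' @param threads Number of worker processes for TF rows (forked via
#'   \pkg{parallel}; results are identical to the serial run).
#' @return Object of class `candidate_network`: list with `mi`, `mask`,
#'   `tf_rows`, `tf_ids`, `gene_ids`.
#' @export
compute_mi_matrix <- function(ranks, tfs, chi2_crit = 7.815, min_points = 8L,
                              threads = 1L) {
  if (!is.matrix(ranks) || !is.integer(ranks))
    stop("ranks must be an integer matrix from rank_transform()")
  tfs <- validate_tf_indices(tfs, ranks)
  n_genes <- nrow(ranks)
  gene_ids <- rownames(ranks)

  row_fun <- function(ti) {
    t_row <- tfs[ti]
    others <- seq_len(n_genes)[-t_row]
    mi <- rep(NA_real_, n_genes)
    mi[others] <- .apmi_batch_cpp(ranks, rep.int(t_row, length(others)),
                                  others, chi2_crit, as.integer(min_points))
    mi
  }
  rows <- if (threads > 1L) {
    parallel::mclapply(seq_along(tfs), row_fun, mc.cores = threads)
  } else {
    lapply(seq_along(tfs), row_fun)
  }
  mi <- do.call(rbind, rows)
  dimnames(mi) <- list(gene_ids[tfs], gene_ids)

  # mirror TF-TF entries from the upper triangle so each unordered pair has
  # a single authoritative value
  for (i in seq_along(tfs)) {
    for (j in seq_along(tfs)) {
      if (i < j) mi[j, tfs[i]] <- mi[i, tfs[j]]
    }
  }

  candidate_network(mi, !is.na(mi), tfs, gene_ids)
}

candidate_network <- function(mi, mask, tf_rows, gene_ids) {
  structure(
    list(mi = mi, mask = mask, tf_rows = as.integer(tf_rows),
         tf_ids = gene_ids[tf_rows], gene_ids = gene_ids),
    class = "candidate_network")
}

#' @export
print.candidate_network <- function(x, ...) {
  cat(sprintf("candidate_network: %d TFs x %d genes, %d edges in mask\n",
              nrow(x$mi), ncol(x$mi), sum(x$mask)))
  invisible(x)
}
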
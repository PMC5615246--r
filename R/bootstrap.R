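#' Bootstrap-resample the samples of an expression matrix
#'
#' Draws M sample columns uniformly with replacement (seeded); gene rows are
#' unchanged and sample ids are carried, so duplicates appear in the
#' resample's colnames.
#'
#' @param matrix Numeric expression matrix.
#' @param seed Integer seed.
#' @return Matrix with the same number of columns, resampled.
#' @export
bootstrap_sample <- function(matrix, seed = 0L) {
  validate_expression(matrix)
  m <- ncol(matrix)
  cols <- with_seed(derive_seed(seed, 4L, 0L), sample.int(m, m, replace = TRUE))
  matrix[, cols, drop = FALSE]
}

#' Create an empty bootstrap aggregate
#'
#' Holds the two reduction matrices of the bootstrap stage: the sum of MI
#' values and the count of occurrences of every edge across bootstrap runs.
#'
#' @param net A `candidate_network` providing the edge-universe shape and
#'   identifiers (its mask is ignored).
#' @return Object of class `bootstrap_aggregate` with zeroed `mi_sum` and
#'   `count` matrices and `n_bootstraps = 0`.
#' @export
new_bootstrap_aggregate <- function(net) {
  check_candidate_network(net)
  zero <- matrix(0, nrow = nrow(net$mi), ncol = ncol(net$mi),
                 dimnames = dimnames(net$mi))
  structure(
    list(mi_sum = zero, count = zero, n_bootstraps = 0L,
         tf_rows = net$tf_rows, tf_ids = net$tf_ids,
         gene_ids = net$gene_ids),
    class = "bootstrap_aggregate")
}

#' Fold one bootstrap run into the aggregate
#'
#' For every edge present in `run_mask`, increments its occurrence count and
#' adds its MI to the running sum.  Accumulation is commutative: the final
#' aggregate does not depend on the order of runs.
#'
#' @param agg A `bootstrap_aggregate`.
#' @param run_mask Boolean edge mask of one pipeline run (post-DPI).
#' @param run_mi MI matrix of the same run.
#' @return The updated aggregate (`n_bootstraps` incremented by one).
#' @export
accumulate <- function(agg, run_mask, run_mi) {
  if (!inherits(agg, "bootstrap_aggregate"))
    stop("agg must be a bootstrap_aggregate")
  if (!identical(dim(run_mask), dim(agg$count)) ||
      !identical(dim(run_mi), dim(agg$mi_sum)))
    stop("run matrices do not match the aggregate's shape")
  agg$count <- agg$count + run_mask
  agg$mi_sum <- agg$mi_sum + ifelse(run_mask, run_mi, 0)
  agg$n_bootstraps <- agg$n_bootstraps + 1L
  agg
}

#' Consolidate bootstrap occurrences into a final network
#'
#' Edges observed across bootstrap runs are tested against a Poisson null of
#' occurrences scattering uniformly over the edge universe.  With
#' `E_possible = N_tf * N_genes - N_tf` non-self directed TF->gene slots,
#' the rate is `lambda = (total occurrences) / E_possible`; an edge seen
#' `k >= 1` times gets `p = P(Poisson(lambda) >= k)`, Bonferroni-corrected
#' over the `E_observed` edges actually seen (`k >= 1`), and is claimed iff
#' the corrected p-value is below `alpha`.  Claimed edges are reported with
#' their mean per-run MI (`mi_sum / k`).  Mirrored TF-TF entries are counted
#' once, in canonical order.
#'
#' @param agg A `bootstrap_aggregate` with at least one accumulated run.
#' @param alpha Significance level for claiming edges (default 0.05).
#' @param lambda Optional override of the Poisson rate (the uniform-scatter
#'   default is one model choice; alternatives can be supplied).
#' @param all_edges If `TRUE`, return every observed edge with a `claimed`
#'   column instead of only the claimed ones.
#' @return Network table of claimed edges (columns `regulator`, `target`,
#'   `mi`, `count`, `p_adj`), sorted as written by [write_network()].
#' @export
consolidate <- function(agg, alpha = 0.05, lambda = NULL, all_edges = FALSE) {
  if (!inherits(agg, "bootstrap_aggregate"))
    stop("agg must be a bootstrap_aggregate")
  if (agg$n_bootstraps < 1L)
    stop("no bootstrap runs accumulated; use the single-run path instead")
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha > 1)
    stop("alpha must be in (0, 1]")

  n_tf <- length(agg$tf_rows)
  n_genes <- length(agg$gene_ids)
  slots <- canonical_slots(agg$tf_rows, n_genes)
  e_possible <- n_tf * n_genes - n_tf
  total <- sum(agg$count[slots])
  if (is.null(lambda)) lambda <- total / e_possible

  idx <- which(slots & agg$count >= 1, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- make_network_table()
    if (all_edges) out$claimed <- logical(0)
    return(out)
  }
  k <- agg$count[idx]
  p <- ppois(k - 1, lambda, lower.tail = FALSE)
  e_observed <- nrow(idx)
  p_adj <- pmin(1, p * e_observed)
  claimed <- p_adj < alpha

  out <- make_network_table(
    regulator = agg$tf_ids[idx[, 1L]],
    target = agg$gene_ids[idx[, 2L]],
    mi = agg$mi_sum[idx] / k,
    count = as.integer(k),
    p_adj = p_adj)
  if (all_edges) {
    out$claimed <- claimed
  } else {
    out <- out[claimed, , drop = FALSE]
    rownames(out) <- NULL
  }
  out[order(out$regulator, out$target, method = "radix"), , drop = FALSE]
}
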
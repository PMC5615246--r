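#' Threshold a candidate network
#'
#' Sets the edge mask to `mi >= threshold` (self entries stay absent); MI
#' values are untouched.
#'
#' @param net A `candidate_network` from [compute_mi_matrix()].
#' @param threshold MI threshold in nats (from [mi_threshold()]).
#' @return The network with its mask replaced.
#' @export
apply_threshold <- function(net, threshold) {
  check_candidate_network(net)
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("threshold must be a single number")
  mask <- !is.na(net$mi) & net$mi >= threshold
  net$mask <- mask
  net
}

#' Data processing inequality pruning over TF-TF-target triangles
#'
#' For a Markov chain g1 -> g2 -> g3 the data processing inequality bounds
#' the indirect dependence: `I(g1;g3) <= min(I(g1;g2), I(g2;g3))`.  ARACNE
#' therefore treats the weakest edge of every fully connected
#' TF-TF-target triangle as presumptively indirect.  For each unordered TF
#' pair (t1, t2) whose TF-TF edge is present in the input mask, and each
#' gene g (distinct from both) with both edges (t1,g) and (t2,g) present, an
#' edge is marked for removal iff its MI is strictly below
#' `min(other two MIs) * (1 - tolerance)`.
#'
#' All comparisons are evaluated against a snapshot of the input mask and
#' removals are applied at the end, so the result does not depend on the
#' order in which triangles are visited — the property that lets every
#' triangle be processed independently.  Ties are retained (strict
#' inequality), degenerate triangles with a repeated node are skipped, and
#' TF-TF removals are applied to both mirrored entries.
#'
#' @param net A thresholded `candidate_network`.
#' @param tolerance DPI tolerance in \[0, 1\]: 0 is strict DPI, 1 disables
#'   pruning entirely.
#' @return The network with pruned mask.
#' @export
dpi <- function(net, tolerance = 0) {
  check_candidate_network(net)
  if (!is.numeric(tolerance) || length(tolerance) != 1L || is.na(tolerance) ||
      tolerance < 0 || tolerance > 1)
    stop("tolerance must be in [0, 1]")

  mask0 <- net$mask
  mi <- net$mi
  keep <- mask0
  tfcol <- net$tf_rows
  n_tf <- length(tfcol)
  col_tf <- integer(ncol(mi))
  col_tf[tfcol] <- seq_len(n_tf)
  fac <- 1 - tolerance

  if (n_tf >= 2L) {
    for (a in seq_len(n_tf - 1L)) {
      for (b in seq.int(a + 1L, n_tf)) {
        ca <- tfcol[a]
        cb <- tfcol[b]
        if (!mask0[a, cb]) next
        mi_ab <- mi[a, cb]
        g <- which(mask0[a, ] & mask0[b, ])
        g <- g[g != ca & g != cb]
        if (!length(g)) next
        mi_ag <- mi[a, g]
        mi_bg <- mi[b, g]
        rm_ag <- mi_ag < pmin(mi_bg, mi_ab) * fac
        rm_bg <- mi_bg < pmin(mi_ag, mi_ab) * fac
        if (any(rm_ag)) {
          for (gg in g[rm_ag]) {
            keep[a, gg] <- FALSE
            if (col_tf[gg] > 0L) keep[col_tf[gg], ca] <- FALSE
          }
        }
        if (any(rm_bg)) {
          for (gg in g[rm_bg]) {
            keep[b, gg] <- FALSE
            if (col_tf[gg] > 0L) keep[col_tf[gg], cb] <- FALSE
          }
        }
        if (any(mi_ab < pmin(mi_ag, mi_bg) * fac)) {
          keep[a, cb] <- FALSE
          keep[b, ca] <- FALSE
        }
      }
    }
  }
  net$mask <- keep
  net
}

check_candidate_network <- function(net) {
  if (!inherits(net, "candidate_network"))
    stop("expected a candidate_network")
  invisible(net)
}

# Logical matrix of counted edge slots: all non-self (TF, gene) entries,
# with each unordered TF-TF pair counted once (canonical order: the TF with
# the smaller gene-row index is the regulator).
canonical_slots <- function(tf_rows, n_genes) {
  n_tf <- length(tf_rows)
  slots <- matrix(TRUE, nrow = n_tf, ncol = n_genes)
  slots[cbind(seq_len(n_tf), tf_rows)] <- FALSE
  if (n_tf >= 2L) {
    for (i in seq_len(n_tf - 1L)) {
      for (j in seq.int(i + 1L, n_tf)) {
        if (tf_rows[i] < tf_rows[j]) slots[j, tf_rows[i]] <- FALSE
        else slots[i, tf_rows[j]] <- FALSE
      }
    }
  }
  slots
}

# Flatten the masked edges of a candidate network into a network table
# (deduplicating mirrored TF-TF entries).
network_from_candidate <- function(net, count = 1L, p_adj = NA_real_) {
  slots <- canonical_slots(net$tf_rows, length(net$gene_ids))
  idx <- which(net$mask & slots, arr.ind = TRUE)
  if (nrow(idx) == 0L) return(make_network_table())
  make_network_table(
    regulator = net$tf_ids[idx[, 1L]],
    target = net$gene_ids[idx[, 2L]],
    mi = net$mi[idx],
    count = rep.int(count, nrow(idx)),
    p_adj = rep.int(p_adj, nrow(idx)))
}
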
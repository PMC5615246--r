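#' Construct a ground-truth regulatory network
#'
#' Container for a known acyclic TF -> target wiring used to validate the
#' pipeline.  `edges` holds direct regulator -> target links with strengths
#' in (0, 1]; `cascade_triples` lists chains t1 -> t2 -> g in which t1 has
#' no direct edge to g, i.e. exactly the indirect shortcuts the data
#' processing inequality is meant to remove.
#'
#' @param tf_ids,target_ids Character vectors of identifiers (disjoint).
#' @param edges Data frame with columns `regulator`, `target`, `weight`.
#' @param cascade_triples Data frame with columns `t1`, `t2`, `g`; every
#'   triple must be backed by edges t1 -> t2 and t2 -> g and must not have a
#'   direct t1 -> g edge.
#' @return Object of class `true_network`.
#' @export
true_network <- function(tf_ids, target_ids,
                         edges = data.frame(regulator = character(),
                                            target = character(),
                                            weight = numeric()),
                         cascade_triples = data.frame(t1 = character(),
                                                      t2 = character(),
                                                      g = character())) {
  tf_ids <- as.character(tf_ids)
  target_ids <- as.character(target_ids)
  if (any(duplicated(c(tf_ids, target_ids))))
    stop("gene identifiers must be unique across TFs and targets")
  if (nrow(edges)) {
    if (any(edges$regulator == edges$target)) stop("self edges not allowed")
    if (!all(edges$regulator %in% tf_ids)) stop("regulators must be TFs")
    if (!all(edges$target %in% c(tf_ids, target_ids)))
      stop("unknown edge target")
    if (any(edges$weight <= 0 | edges$weight > 1))
      stop("edge weights must be in (0, 1]")
  }
  if (nrow(cascade_triples)) {
    key <- paste(edges$regulator, edges$target)
    ok <- paste(cascade_triples$t1, cascade_triples$t2) %in% key &
      paste(cascade_triples$t2, cascade_triples$g) %in% key &
      !(paste(cascade_triples$t1, cascade_triples$g) %in% key)
    if (!all(ok))
      stop("cascade triples inconsistent with direct edges")
  }
  structure(list(tf_ids = tf_ids, target_ids = target_ids,
                 edges = edges, cascade_triples = cascade_triples),
            class = "true_network")
}

#' @export
print.true_network <- function(x, ...) {
  cat(sprintf("true_network: %d TFs, %d targets, %d edges, %d cascade triples\n",
              length(x$tf_ids), length(x$target_ids), nrow(x$edges),
              nrow(x$cascade_triples)))
  invisible(x)
}

#' Generate a random ground-truth regulatory network
#'
#' Each (TF, target) direct edge is present independently with probability
#' `density`.  A fraction `cascade_fraction` of TFs are wired as middle
#' nodes of regulatory chains: each middle TF gets one upstream root TF, and
#' every target it regulates forms a cascade triple (root, middle, target)
#' whenever the root has no direct edge to that target.  The wiring is
#' acyclic by construction (root TFs -> middle TFs -> targets) and link
#' strengths are drawn uniformly from \[0.6, 1\] so that direct dependencies
#' are strong enough to detect at moderate sample sizes.
#'
#' @param n_tf Number of TFs (>= 2).
#' @param n_targets Number of non-TF target genes (>= 1).
#' @param density Probability of each direct TF -> target edge, in \[0, 1\].
#' @param cascade_fraction Fraction of TFs wired as chain middle nodes, in
#'   \[0, 1).
#' @param seed Integer seed; the same arguments always give the same
#'   network.
#' @return A [true_network()].
#' @export
generate_grn <- function(n_tf, n_targets, density, cascade_fraction = 0,
                         seed = 0L) {
  if (n_tf < 2L) stop("need at least 2 TFs")
  if (n_targets < 1L) stop("need at least 1 target")
  if (density < 0 || density > 1) stop("density must be in [0, 1]")
  if (cascade_fraction < 0 || cascade_fraction >= 1)
    stop("cascade_fraction must be in [0, 1)")
  tf_ids <- sprintf("TF%03d", seq_len(n_tf))
  target_ids <- sprintf("G%04d", seq_len(n_targets))

  with_seed(derive_seed(seed, 5L, 0L), {
    n_mid <- min(floor(cascade_fraction * n_tf), n_tf - 1L)
    mid <- if (n_mid > 0L) sample(tf_ids, n_mid) else character()
    roots <- setdiff(tf_ids, mid)

    reg <- character(); tgt <- character()
    # root -> middle TF chain links
    for (t2 in mid) {
      t1 <- if (length(roots) == 1L) roots else sample(roots, 1L)
      reg <- c(reg, t1); tgt <- c(tgt, t2)
    }
    # direct TF -> target links
    if (density > 0) {
      present <- matrix(runif(n_tf * n_targets) < density, n_tf, n_targets)
      hit <- which(present, arr.ind = TRUE)
      reg <- c(reg, tf_ids[hit[, 1L]])
      tgt <- c(tgt, target_ids[hit[, 2L]])
    }
    edges <- data.frame(regulator = reg, target = tgt,
                        weight = runif(length(reg), 0.6, 1),
                        stringsAsFactors = FALSE)

    key <- paste(edges$regulator, edges$target)
    t1s <- character(); t2s <- character(); gs <- character()
    for (t2 in mid) {
      t1 <- edges$regulator[edges$target == t2][1L]
      downstream <- edges$target[edges$regulator == t2 &
                                   edges$target %in% target_ids]
      for (g in downstream) {
        if (!(paste(t1, g) %in% key)) {
          t1s <- c(t1s, t1); t2s <- c(t2s, t2); gs <- c(gs, g)
        }
      }
    }
    true_network(tf_ids, target_ids, edges,
                 data.frame(t1 = t1s, t2 = t2s, g = gs,
                            stringsAsFactors = FALSE))
  })
}

#' Simulate expression data from a ground-truth network
#'
#' Root TFs (no regulators) are i.i.d. standard normal across samples; every
#' regulated gene is `link(weighted sum of its regulators) + N(0, noise_sd)`
#' noise.  Unregulated targets are pure standard-normal background genes.
#' The `sigmoid` link (`tanh`) makes regulation nonlinear while preserving
#' sign, exercising the estimator's ability to capture non-linear
#' association.  Because noise enters each node independently, a cascade
#' t1 -> t2 -> g is an exact Markov chain: g depends on t1 only through t2,
#' so `I(t1;g) <= min(I(t1;t2), I(t2;g))` holds in the generating law — the
#' premise of DPI pruning.
#'
#' @param net A [true_network()].
#' @param n_samples Number of samples (>= 8).
#' @param noise_sd Standard deviation of the additive Gaussian noise (> 0).
#' @param link Link function: `"sigmoid"` (tanh) or `"linear"` (identity).
#' @param seed Integer seed.
#' @return Numeric expression matrix, `(n_tf + n_targets) x n_samples`, rows
#'   ordered TFs first.
#' @export
simulate_expression <- function(net, n_samples, noise_sd,
                                link = c("sigmoid", "linear"), seed = 0L) {
  if (!inherits(net, "true_network")) stop("net must be a true_network")
  if (n_samples < 8L) stop("need at least 8 samples")
  if (!is.numeric(noise_sd) || noise_sd <= 0) stop("noise_sd must be > 0")
  link <- match.arg(link)
  linkfun <- if (link == "sigmoid") tanh else identity

  ids <- c(net$tf_ids, net$target_ids)
  edges <- net$edges
  # topological order via igraph; errors on injected cycles
  order_ids <- if (nrow(edges)) {
    g <- igraph::graph_from_data_frame(
      edges[, c("regulator", "target")], directed = TRUE,
      vertices = data.frame(name = ids))
    if (!igraph::is_dag(g)) stop("cyclic wiring: network must be acyclic")
    names(igraph::topo_sort(g, mode = "out"))
  } else {
    ids
  }

  values <- matrix(NA_real_, nrow = length(ids), ncol = n_samples,
                   dimnames = list(ids,
                                   sprintf("S%04d", seq_len(n_samples))))
  with_seed(derive_seed(seed, 6L, 0L), {
    for (id in order_ids) {
      parents <- edges[edges$target == id, , drop = FALSE]
      if (nrow(parents) == 0L) {
        values[id, ] <- rnorm(n_samples)
      } else {
        drive <- colSums(parents$weight *
                           values[parents$regulator, , drop = FALSE])
        values[id, ] <- linkfun(drive) + rnorm(n_samples, sd = noise_sd)
      }
    }
  })
  values
}

#' Write a simulated dataset to disk
#'
#' Writes the three files the pipeline consumes from a simulation: the
#' expression TSV, the TF list, and the true-network TSV
#' (`Regulator  Target  Weight`) for benchmarking recovered edges.
#'
#' @param net A [true_network()].
#' @param matrix Expression matrix from [simulate_expression()].
#' @param prefix Output path prefix; writes `<prefix>_expression.tsv`,
#'   `<prefix>_tfs.txt`, `<prefix>_truth.tsv`.
#' @return Invisibly, a named character vector of the three paths.
#' @export
write_simulation <- function(net, matrix, prefix) {
  paths <- c(expression = paste0(prefix, "_expression.tsv"),
             tfs = paste0(prefix, "_tfs.txt"),
             truth = paste0(prefix, "_truth.tsv"))
  write_expression(matrix, paths[["expression"]])
  writeLines(net$tf_ids, paths[["tfs"]])
  writeLines(c("Regulator\tTarget\tWeight",
               sprintf("%s\t%s\t%.6g", net$edges$regulator, net$edges$target,
                       net$edges$weight)),
             paths[["truth"]])
  invisible(paths)
}
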
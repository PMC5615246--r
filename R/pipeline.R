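#' Pipeline configuration
#'
#' Bundles and validates every user-facing parameter of [run_pipeline()].
#'
#' @param expression_path Path to the expression TSV.
#' @param tf_path Path to the TF list.
#' @param output_path Path for the network TSV.
#' @param p_value Null-model significance level for the MI threshold
#'   (default 1e-8).
#' @param n0 Number of null MI values (default 100000).
#' @param bootstraps Number of bootstrap runs B; 0 (default) is a single
#'   run without consolidation.
#' @param dpi_tolerance DPI tolerance in \[0, 1\] (default 0, strict DPI).
#' @param chi2_crit Chi-square splitting threshold of the apMI estimator
#'   (default 7.815, the 0.95 quantile at df = 3).
#' @param min_points Minimum rectangle occupancy for splitting (default 8).
#' @param consolidation_alpha Significance level of the bootstrap
#'   consolidation (default 0.05).
#' @param seed Master seed (default 0); bootstrap b uses `seed + b`.
#' @param threads Worker processes for the MI matrix (default 1; results
#'   are identical at any thread count).
#' @param recompute_null_per_bootstrap If `TRUE`, rebuild the null model on
#'   each bootstrap resample instead of reusing the threshold computed once
#'   on the full data.
#' @param verbose Log stage progress via [message()] (default `TRUE`).
#' @return Object of class `aracne_config` (a validated list).
#' @export
aracne_config <- function(expression_path, tf_path, output_path,
                          p_value = 1e-8, n0 = 100000L, bootstraps = 0L,
                          dpi_tolerance = 0, chi2_crit = 7.815,
                          min_points = 8L, consolidation_alpha = 0.05,
                          seed = 0L, threads = 1L,
                          recompute_null_per_bootstrap = FALSE,
                          verbose = TRUE) {
  cfg <- list(expression_path = expression_path, tf_path = tf_path,
              output_path = output_path, p_value = p_value,
              n0 = as.integer(n0), bootstraps = as.integer(bootstraps),
              dpi_tolerance = dpi_tolerance, chi2_crit = chi2_crit,
              min_points = as.integer(min_points),
              consolidation_alpha = consolidation_alpha,
              seed = as.integer(seed), threads = as.integer(threads),
              recompute_null_per_bootstrap =
                isTRUE(recompute_null_per_bootstrap),
              verbose = isTRUE(verbose))
  for (p in c("expression_path", "tf_path", "output_path")) {
    if (!is.character(cfg[[p]]) || length(cfg[[p]]) != 1L || !nzchar(cfg[[p]]))
      stop(p, " must be a nonempty path")
  }
  if (cfg$p_value <= 0 || cfg$p_value > 1) stop("p_value must be in (0, 1]")
  if (cfg$bootstraps < 0L) stop("bootstraps must be >= 0")
  structure(cfg, class = "aracne_config")
}

#' Infer a regulatory network from an in-memory matrix
#'
#' The core of [run_pipeline()], operating on objects rather than files:
#' build the permutation null and MI threshold, rank the data, compute the
#' candidate TF x gene MI matrix, threshold, prune with DPI, and — when
#' `bootstraps >= 1` — repeat over bootstrap resamples and consolidate
#' occurrences under the Poisson model.
#'
#' @param matrix Numeric expression matrix (genes x samples, M >= 8).
#' @param tfs Integer vector of TF row indices.
#' @inheritParams aracne_config
#' @param bootstraps,verbose See [aracne_config()].
#' @return Network table data frame (columns `regulator`, `target`, `mi`,
#'   `count`, `p_adj`; `p_adj` is `NA` when `bootstraps = 0`).
#' @export
aracne_network <- function(matrix, tfs, p_value = 1e-8, n0 = 100000L,
                           bootstraps = 0L, dpi_tolerance = 0,
                           chi2_crit = 7.815, min_points = 8L,
                           consolidation_alpha = 0.05, seed = 0L,
                           threads = 1L,
                           recompute_null_per_bootstrap = FALSE,
                           verbose = TRUE) {
  validate_expression(matrix, min_samples = 8L)
  tfs <- validate_tf_indices(tfs, matrix)
  say <- function(...) if (verbose) message(sprintf(...))
  say("aracnekit: %d genes x %d samples, %d TFs",
      nrow(matrix), ncol(matrix), length(tfs))

  null <- stage("null model", sample_null_mis(
    matrix, tfs, n0 = n0, seed = seed, chi2_crit = chi2_crit,
    min_points = min_points))
  threshold <- stage("null model",
                     mi_threshold(null, p_value))
  say("MI threshold at p = %g: %.6g nats", p_value, threshold)

  single_run <- function(mat, run_seed, thr) {
    ranks <- stage("ranking", rank_transform(mat, run_seed))
    net <- stage("MI matrix", compute_mi_matrix(
      ranks, tfs, chi2_crit = chi2_crit, min_points = min_points,
      threads = threads))
    net <- stage("thresholding", apply_threshold(net, thr))
    n_thr <- sum(net$mask)
    net <- stage("DPI", dpi(net, dpi_tolerance))
    list(net = net, edges_thresholded = n_thr, edges_dpi = sum(net$mask))
  }

  if (bootstraps == 0L) {
    run <- single_run(matrix, seed, threshold)
    say("edges after thresholding: %d; after DPI: %d",
        run$edges_thresholded, run$edges_dpi)
    out <- network_from_candidate(run$net)
  } else {
    agg <- NULL
    for (b in seq_len(bootstraps)) {
      seed_b <- seed + b
      mat_b <- stage("bootstrap", bootstrap_sample(matrix, seed_b))
      thr_b <- if (recompute_null_per_bootstrap) {
        stage("null model", mi_threshold(sample_null_mis(
          mat_b, tfs, n0 = n0, seed = seed_b, chi2_crit = chi2_crit,
          min_points = min_points), p_value))
      } else {
        threshold
      }
      run <- single_run(mat_b, seed_b, thr_b)
      if (is.null(agg)) agg <- new_bootstrap_aggregate(run$net)
      agg <- accumulate(agg, run$net$mask, run$net$mi)
      say("bootstrap %d/%d: %d edges after thresholding, %d after DPI",
          b, bootstraps, run$edges_thresholded, run$edges_dpi)
    }
    out <- stage("consolidation",
                 consolidate(agg, alpha = consolidation_alpha))
    say("consolidated edges claimed at alpha = %g: %d",
        consolidation_alpha, nrow(out))
  }
  out <- out[order(out$regulator, out$target, method = "radix"), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full pipeline from files to a network file
#'
#' One-step orchestration: read the expression matrix and TF list, infer
#' the network with [aracne_network()], and write the result with
#' [write_network()].  A fixed configuration and seed always produce a
#' byte-identical output file.  An empty final network is written as a
#' valid header-only file with a warning.
#'
#' @param config An [aracne_config()].
#' @return The network table, invisibly (also written to
#'   `config$output_path`).
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "aracne_config"))
    stop("config must be an aracne_config")
  matrix <- stage("read expression",
                  read_expression(config$expression_path, min_samples = 8L))
  tfs <- stage("read TF list", read_tf_list(config$tf_path, matrix))
  net <- aracne_network(
    matrix, tfs, p_value = config$p_value, n0 = config$n0,
    bootstraps = config$bootstraps, dpi_tolerance = config$dpi_tolerance,
    chi2_crit = config$chi2_crit, min_points = config$min_points,
    consolidation_alpha = config$consolidation_alpha, seed = config$seed,
    threads = config$threads,
    recompute_null_per_bootstrap = config$recompute_null_per_bootstrap,
    verbose = config$verbose)
  if (nrow(net) == 0L)
    warning("final network is empty; writing header-only file")
  stage("write network", write_network(net, config$output_path))
  invisible(net)
}
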
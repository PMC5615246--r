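test_that("bootstrap resamples draw M columns with replacement, seeded", {
  m <- make_expression(4, 30, seed = 41)
  b1 <- bootstrap_sample(m, seed = 1)
  expect_identical(dim(b1), dim(m))
  expect_true(all(colnames(b1) %in% colnames(m)))
  for (j in seq_len(ncol(b1))) {
    expect_identical(b1[, j], m[, colnames(b1)[j]])
  }
  expect_identical(bootstrap_sample(m, seed = 1), b1)
  expect_false(identical(bootstrap_sample(m, seed = 2), b1))
})

test_that("expected bootstrap coverage of distinct samples is about 1 - 1/e", {
  m <- make_expression(2, 200, seed = 42)
  cov <- mean(vapply(1:60, function(s) {
    length(unique(colnames(bootstrap_sample(m, seed = s)))) / 200
  }, numeric(1)))
  expect_lt(abs(cov - (1 - exp(-1))), 0.02)
})

test_that("accumulation is an order-independent sum/count reduction", {
  set.seed(43)
  net <- random_candidate_network(3, 8)
  agg <- new_bootstrap_aggregate(net)
  expect_identical(agg$n_bootstraps, 0L)
  expect_true(all(agg$count == 0) && all(agg$mi_sum == 0))

  runs <- lapply(1:4, function(i) {
    mask <- matrix(runif(24) < 0.5, 3, 8) & net$mask
    mi <- matrix(runif(24), 3, 8)
    list(mask = mask, mi = mi)
  })
  empty_mask <- matrix(FALSE, 3, 8)

  a1 <- agg
  for (r in runs) a1 <- accumulate(a1, r$mask, r$mi)
  a1 <- accumulate(a1, empty_mask, runs[[1]]$mi)   # empty run: no-op on sums
  a2 <- agg
  for (r in rev(runs)) a2 <- accumulate(a2, r$mask, r$mi)
  a2 <- accumulate(a2, empty_mask, runs[[1]]$mi)

  expect_identical(a1$count, a2$count)
  expect_equal(a1$mi_sum, a2$mi_sum, tolerance = 1e-12)
  expect_identical(a1$n_bootstraps, 5L)
  expect_true(all(a1$mi_sum[a1$count == 0] == 0))
  expect_error(accumulate(a1, matrix(FALSE, 2, 8), runs[[1]]$mi), "shape")

  # edge present in every run reaches count B
  always <- net$mask & Reduce(`&`, lapply(runs, `[[`, "mask"))
  if (any(always)) expect_true(all(a1$count[always] >= 4))
})

# A minimal aggregate with one TF, n_bg background genes, and chosen counts.
single_tf_aggregate <- function(counts, mis = NULL, n_runs = 10L) {
  n_genes <- length(counts) + 1L
  gene_ids <- c("tf", sprintf("g%02d", seq_len(n_genes - 1L)))
  mi <- matrix(c(NA_real_, rep(0.5, n_genes - 1L)), nrow = 1,
               dimnames = list("tf", gene_ids))
  net <- aracnekit:::candidate_network(mi, !is.na(mi), 1L, gene_ids)
  agg <- new_bootstrap_aggregate(net)
  agg$n_bootstraps <- n_runs
  agg$count[1, -1] <- counts
  agg$mi_sum[1, -1] <- if (is.null(mis)) counts * 0.5 else mis
  agg
}

test_that("Poisson consolidation reproduces closed-form tail probabilities", {
  # lambda = 1 arises naturally: one observed edge, E_possible = 1
  gene_ids <- c("tf", "g")
  mi <- matrix(c(NA_real_, 0.7), nrow = 1, dimnames = list("tf", gene_ids))
  net <- aracnekit:::candidate_network(mi, !is.na(mi), 1L, gene_ids)
  agg <- accumulate(new_bootstrap_aggregate(net),
                    matrix(c(FALSE, TRUE), 1, 2), mi)
  out <- consolidate(agg, alpha = 0.05, all_edges = TRUE)
  expect_equal(out$p_adj, 1 - exp(-1), tolerance = 1e-12)  # P(Pois(1) >= 1)
  expect_false(out$claimed)
  expect_identical(nrow(consolidate(agg, alpha = 0.05)), 0L)

  # lambda = 0.1, k = 10: astronomically significant even Bonferroni x 1e6
  agg2 <- single_tf_aggregate(counts = c(10L, rep(0L, 50)))
  out2 <- consolidate(agg2, alpha = 0.05, lambda = 0.1, all_edges = TRUE)
  p_raw <- out2$p_adj / 1L                       # E_observed = 1
  expect_equal(p_raw, poisson_tail_oracle(10, 0.1), tolerance = 1e-15)
  expect_lt(p_raw * 1e6, 0.05)
  expect_true(out2$claimed)
})

test_that("unobserved edges never appear and consolidated MI is the per-run mean", {
  mis <- c(1.2, 0, 0.9)                          # sums over runs
  counts <- c(3L, 0L, 2L)
  agg <- single_tf_aggregate(counts, mis, n_runs = 5L)
  out <- consolidate(agg, alpha = 1, all_edges = TRUE)
  expect_identical(nrow(out), 2L)                # k = 0 edge absent
  expect_equal(out$mi[out$target == "g01"], 1.2 / 3, tolerance = 1e-12)
  expect_equal(out$mi[out$target == "g03"], 0.9 / 2, tolerance = 1e-12)
  expect_error(consolidate(single_tf_aggregate(0L, 0, n_runs = 0L)),
               "no bootstrap runs")
})

test_that("the Poisson tail is monotone in k and lambda against the sum oracle", {
  for (k in 1:8) {
    agg <- single_tf_aggregate(counts = c(k, rep(0L, 30)))
    out <- consolidate(agg, lambda = 1.5, all_edges = TRUE)
    expect_equal(out$p_adj, poisson_tail_oracle(k, 1.5), tolerance = 1e-12)
  }
  p_by_k <- vapply(1:8, function(k) {
    consolidate(single_tf_aggregate(c(k, rep(0L, 30))),
                lambda = 1.5, all_edges = TRUE)$p_adj
  }, numeric(1))
  expect_true(all(diff(p_by_k) < 0))             # decreasing in k

  p_by_lambda <- vapply(c(0.5, 1, 2, 4), function(l) {
    consolidate(single_tf_aggregate(c(3L, rep(0L, 30))),
                lambda = l, all_edges = TRUE)$p_adj
  }, numeric(1))
  expect_true(all(diff(p_by_lambda) > 0))        # increasing in lambda
})

test_that("mirrored TF-TF occurrences are consolidated once, canonically", {
  gene_ids <- c("tfA", "tfB", "g")
  mi <- matrix(c(NA, 0.6, 0.8,
                 0.6, NA, 0.7), nrow = 2, byrow = TRUE,
               dimnames = list(c("tfA", "tfB"), gene_ids))
  net <- aracnekit:::candidate_network(mi, !is.na(mi), 1:2, gene_ids)
  agg <- new_bootstrap_aggregate(net)
  for (i in 1:3) agg <- accumulate(agg, !is.na(mi), mi)
  out <- consolidate(agg, alpha = 1, all_edges = TRUE)
  pair_rows <- out[out$target %in% c("tfA", "tfB"), ]
  expect_identical(nrow(pair_rows), 1L)
  expect_identical(pair_rows$regulator, "tfA")   # smaller row index first
  expect_identical(pair_rows$target, "tfB")
})
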
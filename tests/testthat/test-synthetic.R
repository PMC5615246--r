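test_that("network generation respects density limits and the seed", {
  none <- generate_grn(5, 10, density = 0, seed = 1)
  expect_identical(nrow(none$edges), 0L)

  full <- generate_grn(5, 10, density = 1, seed = 1)
  expect_identical(nrow(full$edges), 50L)
  expect_true(all(full$edges$weight >= 0.6 & full$edges$weight <= 1))

  g1 <- generate_grn(10, 50, density = 0.1, cascade_fraction = 0.4, seed = 7)
  g2 <- generate_grn(10, 50, density = 0.1, cascade_fraction = 0.4, seed = 7)
  expect_identical(g1, g2)
  expect_false(identical(g1, generate_grn(10, 50, 0.1, 0.4, seed = 8)))
})

test_that("cascade triples are true indirect chains", {
  g <- generate_grn(10, 60, density = 0.08, cascade_fraction = 0.5, seed = 3)
  expect_gt(nrow(g$cascade_triples), 0L)
  key <- paste(g$edges$regulator, g$edges$target)
  with(g$cascade_triples, {
    expect_true(all(paste(t1, t2) %in% key))       # TF -> TF link exists
    expect_true(all(paste(t2, g) %in% key))        # TF -> target link exists
    expect_false(any(paste(t1, g) %in% key))       # no direct shortcut
  })
  expect_error(true_network("A", "B",
    edges = data.frame(regulator = "A", target = "A", weight = 0.8)),
    "self edges")
})

test_that("simulation has the declared shape, determinism, and root law", {
  net <- generate_grn(6, 20, density = 0.2, cascade_fraction = 0.3, seed = 5)
  m <- simulate_expression(net, 100, noise_sd = 0.5, seed = 11)
  expect_identical(dim(m), c(26L, 100L))
  expect_identical(rownames(m), c(net$tf_ids, net$target_ids))
  expect_identical(simulate_expression(net, 100, 0.5, seed = 11), m)
  expect_false(identical(simulate_expression(net, 100, 0.5, seed = 12), m))

  # root TFs (no regulators) are standard normal
  roots <- setdiff(net$tf_ids, net$edges$target)
  big <- simulate_expression(net, 4000, noise_sd = 0.5, seed = 13)
  x <- big[roots[1], ]
  expect_gt(stats::shapiro.test(x)$p.value, 1e-3)
  expect_lt(abs(mean(x)), 0.1)
  expect_lt(abs(stats::sd(x) - 1), 0.1)
})

test_that("cyclic wiring is rejected", {
  net <- true_network(c("A", "B"), "G",
    edges = data.frame(regulator = c("A", "B"), target = c("B", "G"),
                       weight = c(0.8, 0.8)))
  net$edges <- rbind(net$edges,
                     data.frame(regulator = "B", target = "A", weight = 0.8))
  expect_error(simulate_expression(net, 50, 0.5, seed = 1), "cyclic")
})

test_that("overwhelming noise drives all pairwise MI to zero", {
  net <- generate_grn(4, 10, density = 0.5, seed = 9)
  m <- simulate_expression(net, 200, noise_sd = 100, seed = 9)
  ranks <- rank_transform(m, seed = 1)
  mis <- aracnekit:::.apmi_batch_cpp(ranks, rep(1:4, each = 10),
                                     rep(5:14, times = 4), 7.815, 8L)
  expect_lt(mean(mis), 0.02)
})

test_that("sample MI of a strong chain respects the data processing inequality", {
  net <- chain_true_network(n_decoy_tfs = 2, n_background = 2)
  hits <- 0L
  for (s in 1:20) {
    m <- simulate_expression(net, 1000, noise_sd = 0.4, link = "linear",
                             seed = s)
    ranks <- rank_transform(m, seed = s)
    mi <- function(a, b) apmi_pair(ranks[a, ], ranks[b, ])$mi
    i12 <- mi("TF1", "TF2"); i2g <- mi("TF2", "G1"); i1g <- mi("TF1", "G1")
    hits <- hits + (i1g < min(i12, i2g))
  }
  expect_gte(hits, 18L)
})

test_that("pipeline recovery on a realistic synthetic network is stable across seeds", {
  stats <- vapply(1:3, function(s) {
    grn <- generate_grn(20, 200, density = 0.05, cascade_fraction = 0.3,
                        seed = s)
    m <- simulate_expression(grn, 500, noise_sd = 0.5, link = "sigmoid",
                             seed = s)
    tfs <- match(grn$tf_ids, rownames(m))
    net <- aracne_network(m, tfs, p_value = 0.05, n0 = 10000, seed = s,
                          verbose = FALSE)
    pred <- paste(net$regulator, net$target)
    truth <- paste(grn$edges$regulator, grn$edges$target)
    casc <- paste(grn$cascade_triples$t1, grn$cascade_triples$g)
    c(recall = sum(pred %in% truth) / length(truth),
      precision = sum(pred %in% truth) / length(pred),
      cascade_removed = 1 - mean(casc %in% pred))
  }, numeric(3))
  expect_true(all(stats["recall", ] > 0.8))
  expect_true(all(stats["precision", ] > 0.7))
  expect_true(all(stats["cascade_removed", ] > 0.9))
  expect_lt(diff(range(stats["recall", ])), 0.05)
  expect_lt(diff(range(stats["precision", ])), 0.05)
})

test_that("simulation files round-trip through the readers", {
  net <- generate_grn(4, 12, density = 0.3, seed = 2)
  m <- simulate_expression(net, 20, noise_sd = 0.5, seed = 2)
  prefix <- tempfile()
  paths <- write_simulation(net, m, prefix)
  back <- read_expression(paths[["expression"]])
  expect_equal(back, m, tolerance = 1e-12)
  tfs <- read_tf_list(paths[["tfs"]], back)
  expect_identical(tfs, 1:4)
  truth <- read.delim(paths[["truth"]])
  expect_identical(nrow(truth), nrow(net$edges))
})
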
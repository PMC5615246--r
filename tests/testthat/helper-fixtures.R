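# Shared fixtures: all data is generated in code, seeded.

make_expression <- function(n_genes, n_samples, seed = 1L) {
  set.seed(seed)
  matrix(rnorm(n_genes * n_samples), nrow = n_genes,
         dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                         sprintf("s%03d", seq_len(n_samples))))
}

write_expression_tsv <- function(lines, path = tempfile(fileext = ".tsv")) {
  writeLines(lines, path)
  path
}

random_rank_pair <- function(m) {
  list(x = sample(0:(m - 1L)), y = sample(0:(m - 1L)))
}

# Correlated bivariate Gaussian sample, rank-transformed to 0-based ranks.
gaussian_rank_pair <- function(m, rho) {
  z1 <- rnorm(m)
  z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(m)
  list(x = rank(z1) - 1L, y = rank(z2) - 1L)
}

# Markov chain TF1 -> TF2 -> G1 embedded among decoy TFs and background
# genes so the permutation null spans enough distinct TF-gene pairs to
# resolve its threshold.
chain_true_network <- function(n_decoy_tfs = 18L, n_background = 100L) {
  true_network(
    c("TF1", "TF2", sprintf("DT%02d", seq_len(n_decoy_tfs))),
    c("G1", sprintf("N%03d", seq_len(n_background))),
    edges = data.frame(regulator = c("TF1", "TF2"),
                       target = c("TF2", "G1"),
                       weight = c(0.9, 0.9), stringsAsFactors = FALSE),
    cascade_triples = data.frame(t1 = "TF1", t2 = "TF2", g = "G1",
                                 stringsAsFactors = FALSE))
}

# Random candidate network with valid invariants: self entries absent,
# TF-TF MI and mask mirrored.
random_candidate_network <- function(n_tf, n_genes, mask_prob = 0.6) {
  gene_ids <- sprintf("g%02d", seq_len(n_genes))
  tf_rows <- sort(sample.int(n_genes, n_tf))
  mi <- matrix(runif(n_tf * n_genes), n_tf, n_genes,
               dimnames = list(gene_ids[tf_rows], gene_ids))
  mask <- matrix(runif(n_tf * n_genes) < mask_prob, n_tf, n_genes)
  for (i in seq_len(n_tf)) {
    mi[i, tf_rows[i]] <- NA_real_
    mask[i, tf_rows[i]] <- FALSE
  }
  for (i in seq_len(n_tf)) for (j in seq_len(n_tf)) {
    if (i < j) {
      mi[j, tf_rows[i]] <- mi[i, tf_rows[j]]
      mask[j, tf_rows[i]] <- mask[i, tf_rows[j]]
    }
  }
  aracnekit:::candidate_network(mi, mask, tf_rows, gene_ids)
}
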
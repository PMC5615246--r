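# Independent reference implementations used as oracles.  They share no
# code with the implementation paths they check.

# Brute-force DPI: enumerate every TF-TF-target triangle explicitly, in an
# arbitrary visiting order, always comparing against the input snapshot.
dpi_oracle <- function(net, tolerance = 0, triangle_order = NULL) {
  mask0 <- net$mask
  mi <- net$mi
  keep <- mask0
  tf_rows <- net$tf_rows
  n_tf <- length(tf_rows)
  n_genes <- ncol(mi)
  col_tf <- integer(n_genes)
  col_tf[tf_rows] <- seq_len(n_tf)
  fac <- 1 - tolerance

  triangles <- list()
  for (a in seq_len(n_tf)) for (b in seq_len(n_tf)) for (g in seq_len(n_genes)) {
    if (a >= b) next
    if (g == tf_rows[a] || g == tf_rows[b]) next
    triangles[[length(triangles) + 1L]] <- c(a, b, g)
  }
  if (!is.null(triangle_order)) triangles <- triangles[triangle_order]

  for (tri in triangles) {
    a <- tri[1L]; b <- tri[2L]; g <- tri[3L]
    ca <- tf_rows[a]; cb <- tf_rows[b]
    if (!(mask0[a, cb] && mask0[a, g] && mask0[b, g])) next
    m_ab <- mi[a, cb]; m_ag <- mi[a, g]; m_bg <- mi[b, g]
    if (m_ag < min(m_bg, m_ab) * fac) {
      keep[a, g] <- FALSE
      if (col_tf[g] > 0L) keep[col_tf[g], ca] <- FALSE
    }
    if (m_bg < min(m_ag, m_ab) * fac) {
      keep[b, g] <- FALSE
      if (col_tf[g] > 0L) keep[col_tf[g], cb] <- FALSE
    }
    if (m_ab < min(m_ag, m_bg) * fac) {
      keep[a, cb] <- FALSE
      keep[b, ca] <- FALSE
    }
  }
  keep
}

# Upper tail P(Poisson(lambda) >= k) by direct cumulative summation.
poisson_tail_oracle <- function(k, lambda) {
  if (k <= 0) return(1)
  i <- 0:(k - 1)
  1 - sum(exp(-lambda) * lambda^i / factorial(i))
}
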
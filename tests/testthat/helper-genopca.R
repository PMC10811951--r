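# shared fixtures: everything is generated in code, no stored data

# small dense binary matrix as a plain base matrix (for hand enumeration)
rand_binary_dense <- function(n, m, pi, seed) {
  as.matrix(sim_binary(n, m, pi, seed))
}

# Jaccard by direct logical-and / logical-or enumeration over column pairs --
# an oracle independent of the crossprod-based implementation
jaccard_by_enumeration <- function(Gd) {
  m <- ncol(Gd)
  J <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) {
      a <- sum(Gd[, i] & Gd[, j])
      o <- sum(Gd[, i] | Gd[, j])
      J[i, j] <- if (o > 0) a / o else 0
    }
  }
  J
}

# intersection counts by enumeration (oracle for A = G'G)
and_counts_by_enumeration <- function(Gd) {
  m <- ncol(Gd)
  A <- matrix(0, m, m)
  for (i in seq_len(m)) {
    for (j in seq_len(m)) A[i, j] <- sum(Gd[, i] & Gd[, j])
  }
  A
}

# absolute cosine between two vectors
abs_cosine <- function(u, v) {
  abs(sum(u * v)) / sqrt(sum(u^2) * sum(v^2))
}

# leading-eigenvector L2 error (up to sign) of the fast path against the
# dense similarity eigendecomposition
leading_pc_error <- function(G, kind = "grm_robust", k = 2, q = 10, seed = 1) {
  F <- similarity_operator(G, kind)
  fast <- fast_eigenvectors(F, k = k, q = q, seed = seed)
  S <- crossprod(materialize_dense(F))
  ed <- eigen(S, symmetric = TRUE)
  u <- ed$vectors[, 1]
  v <- fast$vectors[, 1]
  min(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2)))
}

expect_symmetric <- function(M, tol = 1e-12) {
  expect_lt(max(abs(M - t(M))), tol)
}
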
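test_that("covariance matrix matches hand computation and the textbook oracle", {
  G <- genotype_matrix(rbind(c(1, 0), c(0, 1)), coding = "dosage012")
  expect_equal(covariance_matrix(G),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2, 2), ignore_attr = TRUE)

  # centering annihilates constants
  ones <- genotype_matrix(matrix(1, 4, 3), coding = "binary")
  expect_equal(max(abs(covariance_matrix(ones))), 0)

  # stats::cov on the columns is an independent implementation of the same
  # estimator
  Gd <- as.matrix(sim_dosage(5, 4, 0.1, 0.5, seed = 21))
  expect_equal(unname(covariance_matrix(genotype_matrix(Gd, "dosage012"))),
               unname(stats::cov(Gd)), tolerance = 1e-12, ignore_attr = TRUE)

  expect_error(covariance_matrix(genotype_matrix(matrix(1, 1, 3))), "loci")
})

test_that("Jaccard matrix equals intersection-over-union with the 0/0 -> 0 rule", {
  G <- genotype_matrix(cbind(c(1, 1, 0), c(1, 0, 1)))
  expect_equal(jaccard_matrix(G)[1, 2], 1 / 3)

  dup <- genotype_matrix(cbind(c(1, 1, 0), c(1, 1, 0)))
  expect_equal(jaccard_matrix(dup)[1, 2], 1)

  disj <- genotype_matrix(cbind(c(1, 0, 0), c(0, 1, 0)))
  expect_equal(jaccard_matrix(disj)[1, 2], 0)

  # zero column: empty union entries (incl. its diagonal) are 0, others 1
  gz <- genotype_matrix(cbind(c(1, 1), c(0, 0)))
  J <- jaccard_matrix(gz)
  expect_equal(diag(J), c(1, 0))
  expect_equal(J[1, 2], 0)

  # enumeration oracle on seeded random matrices
  for (s in 1:5) {
    Gd <- rand_binary_dense(8, 6, 0.4, seed = 100 + s)
    expect_equal(unname(jaccard_matrix(genotype_matrix(Gd))),
                 jaccard_by_enumeration(Gd), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }

  expect_error(jaccard_matrix(sim_dosage(4, 4, 0.4, 0.5, seed = 1)), "binary")
})

test_that("intersection counts via crossprod equal logical-and enumeration", {
  for (s in 1:5) {
    Gd <- rand_binary_dense(7, 5, 0.5, seed = 200 + s)
    A <- as.matrix(Matrix::crossprod(genotype_matrix(Gd)$values))
    expect_equal(unname(A), and_counts_by_enumeration(Gd))
  }
})

test_that("approximate Jaccard is a conservative PSD surrogate", {
  G <- genotype_matrix(cbind(c(1, 1, 0), c(1, 0, 1), c(1, 0, 0)))
  Jh <- approx_jaccard_matrix(G)
  expect_equal(Jh[1, 2], 0.25)
  expect_lte(Jh[1, 2], jaccard_matrix(G)[1, 2])

  # two single-one columns sharing their variant: Jhat = 1/2 while J = 1
  tiny <- genotype_matrix(cbind(c(1, 0), c(1, 0)))
  expect_equal(approx_jaccard_matrix(tiny)[1, 2], 0.5)
  expect_equal(jaccard_matrix(tiny)[1, 2], 1)

  # entrywise Jhat <= J wherever the union is nonempty, and Jhat PSD
  for (s in 1:10) {
    G <- sim_binary(30, 12, 0.2, seed = 300 + s)
    J <- jaccard_matrix(G)
    Jh <- approx_jaccard_matrix(G)
    s_col <- colSums(as.matrix(G))
    O <- outer(s_col, s_col, "+") - as.matrix(Matrix::crossprod(G$values))
    expect_true(all(Jh[O > 0] <= J[O > 0] + 1e-12))
    expect_gte(min(eigen(Jh, symmetric = TRUE, only.values = TRUE)$values),
               -1e-10)
  }

  expect_error(approx_jaccard_matrix(genotype_matrix(matrix(0, 2, 2))),
               "all-zero")
})

test_that("weighted Jaccard follows the literal procedure", {
  G <- genotype_matrix(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 1, 1)))
  wj <- weighted_jaccard_matrix(G)
  expect_equal(wj$intermediates$numAlleles, 6)
  expect_equal(wj$intermediates$weights, rep(30, 3))
  expect_equal(unname(wj$matrix),
               matrix(2.5, 3, 3) + diag(2.5, 3), tolerance = 1e-12,
               ignore_attr = TRUE)

  # a singleton row (sum 1) gets weight 0 rather than dividing by zero
  G1 <- genotype_matrix(rbind(c(1, 0, 0), c(1, 1, 0), c(0, 1, 1)))
  w1 <- weighted_jaccard_matrix(G1)
  expect_equal(w1$intermediates$weights[1], 0)
  expect_true(all(is.finite(w1$matrix)))

  # literal inversion rule: a 3x4 all-ones row has sum 4 > n = 3, is
  # inverted to zeros, and ends with weight 0
  G2 <- genotype_matrix(rbind(c(1, 1, 1, 1), c(1, 0, 1, 0), c(0, 1, 0, 0)))
  w2 <- weighted_jaccard_matrix(G2)
  expect_identical(w2$intermediates$invertedRows, 1L)
  expect_equal(w2$intermediates$weights[1], 0)

  # individuals basis flips rows past m/2 instead
  w3 <- weighted_jaccard_matrix(G2, count_basis = "individuals")
  expect_identical(w3$intermediates$numAlleles, 8)
  expect_true(1L %in% w3$intermediates$invertedRows)

  expect_error(weighted_jaccard_matrix(sim_dosage(3, 3, 0.4, 0.5, seed = 1)),
               "binary")
})

test_that("GRM matches hand computation in both flavors", {
  G <- genotype_matrix(rbind(c(0, 2), c(1, 1)), coding = "dosage012")
  expected <- matrix(c(1, -1, -1, 1), 2, 2)
  rob <- grm(G, robust = TRUE)
  expect_equal(unname(rob$matrix), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rob$intermediates$p, c(0.5, 0.5))
  expect_equal(rob$intermediates$ssum, 1)
  expect_equal(unname(grm(G, robust = FALSE)$matrix), expected,
               tolerance = 1e-12, ignore_attr = TRUE)

  # an all-zero locus contributes nothing in either flavor
  Gz <- genotype_matrix(rbind(c(0, 2), c(1, 1), c(0, 0)), coding = "dosage012")
  expect_equal(unname(grm(Gz, TRUE)$matrix), expected, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(unname(grm(Gz, FALSE)$matrix),
               unname(grm(genotype_matrix(rbind(c(0, 2), c(1, 1)),
                                          "dosage012"), FALSE)$matrix) * 2 / 3,
               tolerance = 1e-12)

  # all-monomorphic input: robust flavor is undefined
  mono <- genotype_matrix(matrix(2, 2, 3), coding = "dosage012")
  expect_error(grm(mono, TRUE), "monomorphic")
})

test_that("every similarity output is symmetric and the Gram-like ones are PSD", {
  for (s in 1:5) {
    Gb <- sim_binary(40, 15, 0.25, seed = 400 + s)
    Gd <- sim_dosage(40, 15, 0.05, 0.5, seed = 400 + s)
    mats <- list(covariance_matrix(Gd),
                 jaccard_matrix(Gb),
                 approx_jaccard_matrix(Gb),
                 weighted_jaccard_matrix(Gb)$matrix,
                 grm(Gd, TRUE)$matrix,
                 grm(Gd, FALSE)$matrix)
    for (M in mats) expect_symmetric(M)
    for (M in mats[-2]) {
      ev <- eigen(M, symmetric = TRUE, only.values = TRUE)$values
      expect_gte(min(ev), -1e-10 * max(abs(ev), 1))
    }
  }
})

test_that("seeded search confirms exact Jaccard matrices are numerically PSD", {
  # The binary Jaccard similarity is the min-max (Tanimoto) kernel; the
  # search documents that no genuinely negative eigenvalue turns up (any
  # negativity stays at rounding-noise level relative to the spectral radius)
  res <- find_non_psd_jaccard(n_trials = 60, seed = 17)
  expect_false(res$found)
  expect_gte(res$min_eigenvalue, -1e-12)
})
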
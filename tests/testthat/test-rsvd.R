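test_that("randomized SVD recovers simple spectra", {
  # diagonal case, k = 1 behind the unsafe flag
  r <- randomized_svd(diag(c(3, 1)), k = 1, q = 2, seed = 1, unsafe = TRUE)
  expect_equal(r$values[1], 9, tolerance = 1e-8)
  expect_equal(abs(r$vectors[, 1]), c(1, 0), tolerance = 1e-8)

  # exact rank deficiency: leading right vector collinear with v
  u <- rnorm(15)
  v <- rnorm(8)
  X <- outer(u, v)
  r1 <- randomized_svd(X, k = 2, q = 1, seed = 4)
  expect_gt(abs_cosine(r1$vectors[, 1], v), 1 - 1e-8)
  expect_equal(r1$values[2], 0, tolerance = 1e-8 * r1$values[1])

  # k outside the validity range errors unless overridden
  expect_error(randomized_svd(X, k = 1, q = 1, seed = 1), "unsafe")
  expect_error(randomized_svd(X, k = 7, q = 1, seed = 1), "validity")
})

test_that("randomized SVD matches the dense SVD oracle when gaps are healthy", {
  set.seed(77)
  for (s in 1:5) {
    X <- matrix(rnorm(40 * 20), 40, 20)
    sv <- svd(X)
    r <- randomized_svd(X, k = 3, q = 10, seed = 700 + s)
    gaps <- (sv$d[1:3]^2 - sv$d[2:4]^2) / sv$d[1]^2
    for (j in 1:3) {
      if (gaps[j] >= 0.05) {
        expect_gt(abs_cosine(r$vectors[, j], sv$v[, j]), 0.999)
      }
    }
    expect_equal(r$values, sv$d[1:3]^2, tolerance = 1e-3)
    # orthonormal output
    expect_lt(max(abs(crossprod(r$vectors) - diag(3))), 1e-8)
  }
})

test_that("factored fast path equals the dense-input algorithm under a shared seed", {
  # hand case: robust GRM of the 2x2 example has spectrum {2, 0}
  Fg <- factor_grm(genotype_matrix(rbind(c(0, 2), c(1, 1)), "dosage012"), TRUE)
  r <- fast_eigenvectors(Fg, k = 1, q = 4, seed = 5, unsafe = TRUE)
  expect_equal(r$values[1], 2, tolerance = 1e-10)
  expect_equal(abs(r$vectors[, 1]), c(1, 1) / sqrt(2), tolerance = 1e-10)

  for (s in 1:10) {
    Gb <- sim_binary(80, 24, 0.2, seed = 800 + s)
    Fo <- switch(1 + (s %% 3),
                 factor_covariance(Gb),
                 factor_approx_jaccard(Gb),
                 factor_weighted_jaccard(Gb))
    fast <- fast_eigenvectors(Fo, k = 2, q = 6, seed = 900 + s)
    dense <- randomized_svd(materialize_dense(Fo), k = 2, q = 6, seed = 900 + s)
    expect_lt(max(abs(fast$vectors - dense$vectors)), 1e-8)
    expect_equal(fast$values, dense$values, tolerance = 1e-8)
  }
})

test_that("fast path reproduces dense eigendecompositions of the similarity", {
  G <- sim_binary(500, 100, 0.1, seed = 31)
  Fo <- factor_covariance(G)
  r <- fast_eigenvectors(Fo, k = 2, q = 10, seed = 32)
  ed <- eigen(covariance_matrix(G), symmetric = TRUE)
  relgap <- (ed$values[1:2] - ed$values[2:3]) / ed$values[1]
  for (j in 1:2) {
    if (relgap[j] >= 0.05) {
      expect_gt(abs_cosine(r$vectors[, j], ed$vectors[, j]), 0.999)
    }
  }
  # eigenvalue estimates are only gap-limited accurate on a flat spectrum
  expect_equal(r$values, ed$values[1:2], tolerance = 0.05)
})

test_that("reconstruction error is monotone in q on average and degeneracy is flagged", {
  set.seed(88)
  qs <- c(0, 2, 6)
  errs <- matrix(0, 20, length(qs))
  for (s in 1:20) {
    X <- matrix(rnorm(30 * 15), 30, 15)
    for (iq in seq_along(qs)) {
      r <- randomized_svd(X, k = 3, q = qs[iq], seed = 1000 + s)
      Xhat <- r$left %*% (r$singular_values * t(r$vectors))
      errs[s, iq] <- norm(X - Xhat, "2")
    }
  }
  avg <- colMeans(errs)
  expect_true(all(diff(avg) <= 1e-12))

  z <- fast_eigenvectors(factored_operator(1, c(1, 1, 1), c(0, 0, 0), "column",
                                           genotype_matrix(matrix(0, 3, 2),
                                                           allow_empty = TRUE)),
                         k = 1, q = 2, seed = 1, unsafe = TRUE)
  expect_true(z$degenerate)
  expect_equal(z$values, 0)
})

test_that("the a-priori SVD accuracy bound evaluates correctly", {
  expect_equal(svd_error_bound(100, 100, 2, 2, 1),
               (1 + 4 * sqrt(200))^(1 / 5), tolerance = 1e-12)
  expect_equal(svd_error_bound(60, 30, 3, 4, 0), 0)
  # q -> infinity tightens to sigma_{k+1}
  expect_equal(svd_error_bound(50, 50, 3, 10000, 2), 2, tolerance = 1e-3)
  expect_error(svd_error_bound(100, 100, 1, 2, 1), "valid")
})

test_that("power method converges on small closed-form spectra", {
  A1 <- diag(c(2, 1))
  p1 <- power_method(function(y) A1 %*% y, 2, seed = 3)
  expect_equal(p1$value, 2, tolerance = 1e-6)
  expect_equal(abs(p1$vector), c(1, 0), tolerance = 1e-6)

  A2 <- matrix(c(2, 1, 1, 2), 2, 2)
  p2 <- power_method(function(y) A2 %*% y, 2, seed = 3)
  expect_equal(p2$value, 3, tolerance = 1e-8)
  expect_equal(abs(p2$vector), c(1, 1) / sqrt(2), tolerance = 1e-6)

  p3 <- power_method(function(y) y, 4, seed = 9)
  expect_equal(p3$value, 1, tolerance = 1e-12)

  expect_warning(p0 <- power_method(function(y) 0 * y, 3, seed = 1),
                 "annihilated")
  expect_equal(p0$value, 0)
  expect_true(p0$degenerate)
})

test_that("operator applications are counted, matching the 2q+2 closed form", {
  G <- sim_binary(100, 30, 0.1, seed = 55)
  for (q in c(0L, 3L, 10L)) {
    r <- fast_eigenvectors(factor_covariance(G), k = 2, q = q, seed = 1)
    expect_identical(r$ops$matvec, q + 1L)
    expect_identical(r$ops$rmatvec, q + 1L)
  }
})
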
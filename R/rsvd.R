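#' @name rsvd
#' @title Randomized SVD for similarity-matrix eigenvectors
#'
#' @description
#' The top-\eqn{k} eigenvectors of \eqn{X^\top X} are the leading right
#' singular vectors of \eqn{X}. They are obtained from a Gaussian sketch with
#' \eqn{2k} columns, \eqn{q} power iterations, a QR range basis and one small
#' exact SVD; the generic variant (\code{randomized_svd}) takes a dense
#' \eqn{X}, the fast variant (\code{fast_eigenvectors}) takes a
#' \code{\link{factored_operator}} and performs every product through
#' \code{\link{op_matvec}}/\code{\link{op_rmatvec}}, so neither the
#' similarity matrix nor a dense \eqn{X} is ever formed.
#'
#' Because the eigenvectors of the \eqn{m \times m} similarity matrix have
#' length \eqn{m}, the sketch is run in the orientation that keeps the range
#' basis \eqn{Q} in \eqn{R^{m \times 2k}}: the test matrix
#' \eqn{\Omega \in R^{n \times 2k}} is multiplied through
#' \eqn{Y = (X^\top X)^q X^\top \Omega}, \eqn{Q} is the QR basis of \eqn{Y},
#' \eqn{B = Q^\top X^\top} is the \eqn{2k \times n} projected matrix, and the
#' returned vectors are \eqn{U = Q \tilde U \in R^{m \times k}} from the
#' truncated small SVD \eqn{B = \tilde U \Sigma \hat V^\top}. With the same
#' seed the two variants perform identical arithmetic up to sparse/dense
#' rounding.
#'
#' @details
#' The validity range \eqn{2 \le k \le 0.5\min(m,n)} comes with the accuracy
#' guarantee of \code{\link{svd_error_bound}}; \code{unsafe = TRUE} disables
#' the range check (e.g. \eqn{k = 1} on toy matrices). The default power
#' exponent is \eqn{q = 2k}; larger values give higher accuracy. Returned
#' eigenvectors are sign-normalised so each column's largest-magnitude entry
#' is positive (eigenvectors are only defined up to sign). An optional QR
#' re-orthonormalisation between power iterations (\code{stabilize = TRUE})
#' guards against floating-point range collapse at large \eqn{q}; default off,
#' matching the literal algorithm.
NULL

# shared sketch core: mv(Y) = X %*% Y (m -> n), rmv(Z) = t(X) %*% Z (n -> m)
rsvd_core <- function(mv, rmv, n, m, k, q, seed, unsafe = FALSE,
                      stabilize = FALSE, method = "algorithm1") {
  stopifnot(k >= 1, q >= 0)
  if (!unsafe && !(k >= 2 && k <= 0.5 * min(m, n))) {
    stop("k outside the validity range 2 <= k <= 0.5*min(m, n); ",
         "pass unsafe = TRUE to override", call. = FALSE)
  }
  l <- min(2L * k, m) # sketch width; cannot exceed the range dimension
  Omega <- with_seed(seed, matrix(stats::rnorm(n * l), n, l))
  Y <- rmv(Omega)                      # m x l
  if (q > 0) {
    for (i in seq_len(q)) {
      if (stabilize) Y <- qr.Q(qr(Y))
      Y <- rmv(mv(Y))
    }
  }
  Q <- qr.Q(qr(Y))                     # m x l orthonormal range basis
  B <- t(mv(Q))                        # (X Q)' = Q'X', l x n
  sv <- svd(B)                         # small exact SVD, truncated to k below
  kk <- min(k, length(sv$d))
  U <- Q %*% sv$u[, seq_len(kk), drop = FALSE]
  d <- sv$d[seq_len(kk)]
  # X' ~ Q B = Q U~ Sigma V^', so V^'s columns are the matching left singular
  # vectors of X -- no extra operator application needed for reconstruction
  L <- sv$v[, seq_len(kk), drop = FALSE]
  # deterministic sign: largest-magnitude entry of each eigenvector positive
  for (j in seq_len(kk)) {
    i0 <- which.max(abs(U[, j]))
    if (U[i0, j] < 0) {
      U[, j] <- -U[, j]
      L[, j] <- -L[, j]
    }
  }
  structure(list(vectors = U, values = d^2, singular_values = d, left = L,
                 k = k, q = q, seed = seed, method = method,
                 degenerate = all(d <= 0)),
            class = "eigen_result")
}

#' @exportS3Method base::print
print.eigen_result <- function(x, ...) {
  cat(sprintf("<eigen_result> method=%s k=%d q=%d seed=%s\n eigenvalues: %s\n",
              x$method, x$k, x$q, format(x$seed),
              paste(signif(x$values, 6), collapse = ", ")))
  invisible(x)
}

#' @rdname rsvd
#' @param X dense numeric matrix (\eqn{n \times m}).
#' @param k number of eigenvectors sought.
#' @param q power-iteration exponent (default \eqn{2k}).
#' @param seed integer seed for the Gaussian test matrix.
#' @param unsafe disable the \eqn{k} validity-range check.
#' @param stabilize re-orthonormalise between power iterations.
#' @return an \code{eigen_result}: \code{vectors} (\eqn{m \times k},
#'   orthonormal columns, the principal components of \eqn{X^\top X}),
#'   \code{values} (squared singular values, nonincreasing),
#'   \code{singular_values}, \code{left} (\eqn{n \times k} left singular
#'   vectors, for reconstruction), \code{k}, \code{q}, \code{seed},
#'   \code{method}, \code{degenerate}.
#' @export
randomized_svd <- function(X, k, q = 2 * k, seed = 1L, unsafe = FALSE,
                           stabilize = FALSE) {
  X <- as.matrix(X)
  rsvd_core(mv = function(Y) X %*% Y,
            rmv = function(Z) crossprod(X, Z),
            n = nrow(X), m = ncol(X), k = k, q = q, seed = seed,
            unsafe = unsafe, stabilize = stabilize, method = "algorithm1")
}

#' @rdname rsvd
#' @param F a \code{\link{factored_operator}}.
#' @return \code{fast_eigenvectors} additionally records \code{ops}, the
#'   instrumented operator-application counts
#'   (\code{matvec}/\code{rmatvec} block calls, \eqn{q+1} each) and
#'   \code{work_proxy}, the deterministic per-application cost surrogate
#'   \eqn{nnz(G) + n + m} summed over applications; both support asserting
#'   the \eqn{O(qk \cdot nm + k^2(n+m))} complexity contract by counting
#'   rather than timing.
#' @export
fast_eigenvectors <- function(F, k, q = 2 * k, seed = 1L, unsafe = FALSE,
                              stabilize = FALSE) {
  stopifnot(inherits(F, "factored_operator"))
  counts <- new.env(parent = emptyenv())
  counts$mv <- 0L
  counts$rmv <- 0L
  res <- rsvd_core(
    mv = function(Y) {
      counts$mv <- counts$mv + 1L
      op_matvec(F, Y)
    },
    rmv = function(Z) {
      counts$rmv <- counts$rmv + 1L
      op_rmatvec(F, Z)
    },
    n = F$n, m = F$m, k = k, q = q, seed = seed,
    unsafe = unsafe, stabilize = stabilize, method = "algorithm2")
  res$ops <- list(matvec = counts$mv, rmatvec = counts$rmv)
  res$work_proxy <- (counts$mv + counts$rmv) *
    (length(F$G$values@x) + F$n + F$m)
  res
}

#' A-priori accuracy bound for the randomized SVD
#'
#' Expected spectral-norm error of the rank-\eqn{k} randomized SVD with a
#' \eqn{2k}-column Gaussian sketch and \eqn{q} power iterations:
#' \deqn{E\|X - U\Sigma V^\top\| \le
#'   \left[1 + 4\sqrt{\frac{2\min(m,n)}{k-1}}\right]^{1/(2q+1)} \sigma_{k+1},}
#' valid for \eqn{2 \le k \le 0.5\min(m,n)}. As \eqn{q \to \infty} the
#' bracket's exponent vanishes and the bound tightens to \eqn{\sigma_{k+1}},
#' the best possible rank-\eqn{k} error.
#'
#' @param m,n dimensions of \eqn{X}.
#' @param k target rank (>= 2; the bound divides by \eqn{k-1}).
#' @param q power-iteration exponent.
#' @param sigma_next the \eqn{(k+1)}th singular value of \eqn{X}.
#' @return the bound (same units as \code{sigma_next}).
#' @export
svd_error_bound <- function(m, n, k, q, sigma_next) {
  stopifnot(sigma_next >= 0, q >= 0)
  if (!(k >= 2 && k <= 0.5 * min(m, n))) {
    stop("bound valid only for 2 <= k <= 0.5*min(m, n)", call. = FALSE)
  }
  (1 + 4 * sqrt(2 * min(m, n) / (k - 1)))^(1 / (2 * q + 1)) * sigma_next
}

#' Power method (Von Mises iteration) for the leading eigenpair
#'
#' Iterates \eqn{y \leftarrow A y} with normalisation for a fixed number of
#' iterations from a seeded random start and returns the Rayleigh quotient
#' and unit vector. Baseline method for leading-eigenvector computations and
#' for the eigengap estimates in the bound machinery.
#'
#' @param apply function of one vector returning \eqn{A y} for a symmetric
#'   positive semidefinite operator \eqn{A}.
#' @param dim dimension of the operator.
#' @param iters fixed iteration count (default 100).
#' @param seed integer seed for the start vector.
#' @return list with \code{value} (Rayleigh quotient), \code{vector} (unit),
#'   and \code{degenerate} (TRUE when the iterate collapsed to zero, in which
#'   case the eigenvalue is reported as 0 with a warning).
#' @export
power_method <- function(apply, dim, iters = 100L, seed = 1L) {
  stopifnot(dim >= 1, iters >= 1)
  y <- with_seed(seed, stats::rnorm(dim))
  y <- y / sqrt(sum(y^2))
  for (i in seq_len(iters)) {
    z <- as.numeric(apply(y))
    nz <- sqrt(sum(z^2))
    if (nz == 0) {
      warning("power method: operator annihilated the iterate; ",
              "returning eigenvalue 0")
      return(list(value = 0, vector = y, degenerate = TRUE))
    }
    y <- z / nz
  }
  list(value = sum(y * as.numeric(apply(y))), vector = y, degenerate = FALSE)
}
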
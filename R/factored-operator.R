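#' Factored similarity operator
#'
#' The unified representation behind the fast eigenvector path. Each
#' decomposable similarity matrix \eqn{S} is written as \eqn{S = X^\top X}
#' with
#' \deqn{X = a \cdot v \odot_r (G \ominus_r w) \quad (axis = "row")}
#' \deqn{X = a \cdot v \odot_c (G \ominus_c w) \quad (axis = "column")}
#' i.e. entrywise \eqn{X_{ij} = a\, v_j (G_{ij} - w_j)} for the row axis
#' (\eqn{v, w \in R^m}) and \eqn{X_{ij} = a\, v_i (G_{ij} - w_i)} for the
#' column axis (\eqn{v, w \in R^n}). The centering \eqn{\ominus} and scaling
#' \eqn{\odot} stay symbolic: \code{G} is stored sparse and \eqn{X} is never
#' materialised, because subtracting a dense centering vector from every
#' row/column would destroy sparsity. All products with \eqn{X} go through
#' \code{\link{op_matvec}} / \code{\link{op_rmatvec}}, which apply the
#' centering as an analytic rank-one correction using \eqn{O(n+m)} auxiliary
#' storage per vector.
#'
#' @param a positive scalar normalizer.
#' @param v,w multiplier and centering vectors on the chosen axis.
#' @param axis \code{"row"} or \code{"column"}.
#' @param G a \code{\link{genotype_matrix}} (possibly preprocessed, e.g.
#'   minor-allele inverted for the weighted Jaccard).
#' @param kind label of the similarity the operator factors.
#' @return object of class \code{"factored_operator"} with fields
#'   \code{a, v, w, axis, G, n, m, kind}.
#' @export
factored_operator <- function(a, v, w, axis = c("row", "column"), G,
                              kind = "custom") {
  axis <- match.arg(axis)
  G <- as_genotype_matrix(G)
  len <- if (axis == "row") G$m else G$n
  stopifnot(is.numeric(a), length(a) == 1L, a > 0,
            length(v) == len, length(w) == len,
            all(is.finite(v)), all(is.finite(w)))
  structure(list(a = a, v = as.numeric(v), w = as.numeric(w), axis = axis,
                 G = G, n = G$n, m = G$m, kind = kind),
            class = "factored_operator")
}

#' @exportS3Method
dim.factored_operator <- function(x) c(x$n, x$m)

#' @exportS3Method base::print
print.factored_operator <- function(x, ...) {
  cat(sprintf("<factored_operator> %s: X = a*v (*) (G (-) w), axis=%s, %d x %d, a=%g\n",
              x$kind, x$axis, x$n, x$m, x$a))
  invisible(x)
}

#' Factored form of the covariance matrix
#'
#' \eqn{a = 1/\sqrt{n-1}}, \eqn{v = 1_m}, \eqn{w =} column means of \eqn{G},
#' on the row axis, so that \eqn{X^\top X} is \code{\link{covariance_matrix}}.
#'
#' @param G genotype matrix (dosage or binary).
#' @return a \code{\link{factored_operator}}.
#' @export
factor_covariance <- function(G) {
  G <- as_genotype_matrix(G)
  if (G$n < 2) stop("covariance needs at least 2 loci", call. = FALSE)
  factored_operator(a = 1 / sqrt(G$n - 1),
                    v = rep(1, G$m),
                    w = as.numeric(Matrix::colMeans(G$values)),
                    axis = "row", G = G, kind = "covariance")
}

#' Factored form of the approximate Jaccard matrix
#'
#' \eqn{a = 1/\sqrt{2\max(s)}}, \eqn{v = 1_m}, \eqn{w = 0_m} on the row axis:
#' \eqn{X^\top X = G^\top G / (2\max(s)) = \hat J}. The exact Jaccard matrix
#' admits no such factorization (a Gram form forces positive
#' semidefiniteness, and more to the point the union count in its
#' denominator is not bilinear in the columns), which is the reason the
#' approximation exists.
#'
#' @param G binary genotype matrix.
#' @return a \code{\link{factored_operator}}.
#' @export
factor_approx_jaccard <- function(G) {
  G <- as_genotype_matrix(G)
  check_coding(G, "binary")
  smax <- max(Matrix::colSums(G$values))
  if (smax == 0) stop("approximate Jaccard undefined for an all-zero matrix",
                      call. = FALSE)
  factored_operator(a = 1 / sqrt(2 * smax),
                    v = rep(1, G$m), w = rep(0, G$m),
                    axis = "row", G = G, kind = "approx_jaccard")
}

#' Factored form of the weighted Jaccard matrix
#'
#' Minor-allele inversion is applied in this constructor and the inverted
#' matrix is stored in the operator, keeping the product code generic. Then
#' \eqn{a = 1/\sqrt{4n}}, \eqn{v = \sqrt{weights}} (componentwise),
#' \eqn{w = 0_n} on the column axis.
#'
#' @param G binary genotype matrix.
#' @inheritParams weighted_jaccard_matrix
#' @return a \code{\link{factored_operator}}.
#' @export
factor_weighted_jaccard <- function(G, count_basis = c("loci", "individuals")) {
  G <- as_genotype_matrix(G)
  prep <- wj_prepare(G, count_basis)
  factored_operator(a = 1 / sqrt(4 * G$n),
                    v = sqrt(prep$weights), w = rep(0, G$n),
                    axis = "column",
                    G = genotype_matrix(prep$G, coding = "binary"),
                    kind = "weighted_jaccard")
}

#' Factored form of the genomic relationship matrix
#'
#' Column axis with centering \eqn{w = 2p}. Robust: \eqn{a = 1/\sqrt{s}},
#' \eqn{v = 1_n} with \eqn{s = \sum_i 2p_i(1-p_i)}. Non-robust:
#' \eqn{a = 1/\sqrt{n}}, \eqn{v = 1/\sqrt{q}} componentwise, with
#' \eqn{v_i = 0} for monomorphic loci (\eqn{q_i = 0}).
#'
#' @param G genotype matrix (dosage or binary).
#' @param robust robust or non-robust flavor.
#' @return a \code{\link{factored_operator}}.
#' @export
factor_grm <- function(G, robust = TRUE) {
  G <- as_genotype_matrix(G)
  p <- as.numeric(Matrix::rowMeans(G$values)) / 2
  qvec <- 2 * p * (1 - p)
  ssum <- sum(qvec)
  if (robust) {
    if (ssum <= 0) stop("robust GRM undefined: all loci are monomorphic",
                        call. = FALSE)
    factored_operator(a = 1 / sqrt(ssum), v = rep(1, G$n), w = 2 * p,
                      axis = "column", G = G, kind = "grm_robust")
  } else {
    factored_operator(a = 1 / sqrt(G$n),
                      v = ifelse(qvec > 0, 1 / sqrt(qvec), 0), w = 2 * p,
                      axis = "column", G = G, kind = "grm_nonrobust")
  }
}

#' Structured products with a factored operator
#'
#' \code{op_matvec} computes \eqn{X y} and \code{op_rmatvec} computes
#' \eqn{X^\top z} without forming \eqn{X}: the sparse product with \eqn{G} is
#' separated from the centering, which collapses to a rank-one correction.
#' For the column axis,
#' \eqn{X y = a\,(v \circ (G y) - (v \circ w)\,\Sigma y)} and
#' \eqn{X^\top z = a\,(G^\top (v \circ z) - 1_m \langle v \circ w, z\rangle)};
#' the row axis is analogous with column sums. Both accept a vector or a
#' matrix of columns; auxiliary storage is \eqn{O(n+m)} per column.
#'
#' @param F a \code{\link{factored_operator}}.
#' @param y length-\eqn{m} vector (or \eqn{m \times c} matrix).
#' @param z length-\eqn{n} vector (or \eqn{n \times c} matrix).
#' @return a dense vector/matrix: \eqn{Xy} of length \eqn{n}, \eqn{X^\top z}
#'   of length \eqn{m}.
#' @export
op_matvec <- function(F, y) {
  y <- as.matrix(y)
  if (nrow(y) != F$m) stop(sprintf("expected length-%d input, got %d",
                                   F$m, nrow(y)), call. = FALSE)
  Gm <- F$G$values
  out <- if (F$axis == "column") {
    # X = a diag(v) (G - w 1_m'):  Xy = a (v o (G y) - (v o w) sum(y))
    F$a * (F$v * as.matrix(Gm %*% y) - outer(F$v * F$w, colSums(y)))
  } else {
    # X = a (G - 1_n w') diag(v):  Xy = a (G (v o y) - 1_n <w o v, y>)
    F$a * (as.matrix(Gm %*% (F$v * y)) -
             matrix(colSums((F$w * F$v) * y), F$n, ncol(y), byrow = TRUE))
  }
  if (ncol(out) == 1L) as.numeric(out) else out
}

#' @rdname op_matvec
#' @export
op_rmatvec <- function(F, z) {
  z <- as.matrix(z)
  if (nrow(z) != F$n) stop(sprintf("expected length-%d input, got %d",
                                   F$n, nrow(z)), call. = FALSE)
  Gm <- F$G$values
  out <- if (F$axis == "column") {
    # X'z = a (G' (v o z) - 1_m <v o w, z>)
    F$a * (as.matrix(Matrix::crossprod(Gm, F$v * z)) -
             matrix(colSums((F$v * F$w) * z), F$m, ncol(z), byrow = TRUE))
  } else {
    # X'z = a (v o (G'z) - (v o w) sum(z))
    F$a * (F$v * as.matrix(Matrix::crossprod(Gm, z)) -
             outer(F$v * F$w, colSums(z)))
  }
  if (ncol(out) == 1L) as.numeric(out) else out
}

#' Dense materialisation of a factored operator (test oracle)
#'
#' Literal dense evaluation of \eqn{X = a \cdot v \odot (G \ominus w)}.
#' Guarded: refuses matrices beyond \code{max_elements} entries, because
#' densifying is exactly what the operator exists to avoid. Intended for
#' oracle cross-checks at desk scale only.
#'
#' @param F a \code{\link{factored_operator}}.
#' @param max_elements refusal threshold on \eqn{n \times m}.
#' @return dense \eqn{n \times m} matrix.
#' @export
materialize_dense <- function(F, max_elements = 2e7) {
  if (as.double(F$n) * F$m > max_elements) {
    stop("refusing to densify: n*m exceeds max_elements", call. = FALSE)
  }
  Gd <- as.matrix(F$G$values)
  if (F$axis == "column") {
    F$a * (F$v * (Gd - F$w)) # v, w recycle down columns (per row)
  } else {
    F$a * sweep(sweep(Gd, 2L, F$w), 2L, F$v, "*")
  }
}
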
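#' @name similarity
#' @title Dense reference similarity matrices
#'
#' @description
#' Literal, dense implementations of the five genomic similarity matrices.
#' These are the package's correctness oracles: every factored operator in
#' \code{\link{factor_covariance}} and friends must reproduce them exactly
#' (to floating-point tolerance) as \eqn{X^\top X}. They are deliberately
#' straightforward and materialise dense \eqn{m \times m} results, which is
#' exactly what the factored randomized-SVD path avoids; do not use them at
#' biobank scale.
#'
#' All functions accept a \code{\link{genotype_matrix}} (or anything
#' \code{\link{as_genotype_matrix}} can coerce). Outputs carry a
#' \code{"kind"} attribute naming the similarity.
NULL

# symmetrize away rounding asymmetry from BLAS order of operations
sym <- function(M) (M + t(M)) / 2

#' @rdname similarity
#' @param G genotype matrix (dosage or binary coding).
#' @return \code{covariance_matrix}: the \eqn{m \times m} sample covariance of
#'   individuals, \eqn{\frac{1}{n-1} C^\top C} with \eqn{C} the column-centered
#'   genotypes.
#' @export
covariance_matrix <- function(G) {
  G <- as_genotype_matrix(G)
  if (G$n < 2) stop("covariance needs at least 2 loci (division by n-1)",
                    call. = FALSE)
  Gd <- as.matrix(G$values)
  C <- sweep(Gd, 2L, colMeans(Gd))
  structure(sym(crossprod(C) / (G$n - 1)), kind = "covariance")
}

# intersection/union counts shared by the Jaccard family
jaccard_counts <- function(G) {
  s <- Matrix::colSums(G$values)
  A <- as.matrix(Matrix::crossprod(G$values))
  O <- outer(s, s, "+") - A
  list(A = A, O = O, colsums = s)
}

#' @rdname similarity
#' @return \code{jaccard_matrix}: pairwise intersection-over-union of the
#'   binary variant profiles, \eqn{J_{ij} = |g_i \wedge g_j| / |g_i \vee g_j|}.
#'   Entries with an empty union (two all-zero columns, including the diagonal
#'   of an all-zero column) are defined as 0: no shared variants carries no
#'   evidence of similarity, and the convention avoids NaN propagation.
#' @export
jaccard_matrix <- function(G) {
  G <- as_genotype_matrix(G)
  check_coding(G, "binary")
  cts <- jaccard_counts(G)
  J <- ifelse(cts$O > 0, cts$A / cts$O, 0)
  structure(sym(J), kind = "jaccard")
}

#' @rdname similarity
#' @return \code{approx_jaccard_matrix}: the conservative Gram-form surrogate
#'   \eqn{\hat J = A / (2 \max(s))}, where \eqn{A = G^\top G} and \eqn{s} are
#'   the column sums. Since the union of two columns can never exceed
#'   \eqn{2\max(s)}, \eqn{\hat J \le J} entrywise wherever the union is
#'   non-empty, so the approximation never overestimates similarity; being
#'   proportional to a Gram matrix it is also positive semidefinite, which is
#'   what makes the factored randomized SVD applicable.
#' @export
approx_jaccard_matrix <- function(G) {
  G <- as_genotype_matrix(G)
  check_coding(G, "binary")
  cts <- jaccard_counts(G)
  smax <- max(cts$colsums)
  if (smax == 0) stop("approximate Jaccard undefined for an all-zero matrix",
                      call. = FALSE)
  structure(sym(cts$A / (2 * smax)), kind = "approx_jaccard")
}

# shared weighted-Jaccard preprocessing: minor-allele inversion and the
# rarity weights. Returns the (possibly inverted) sparse matrix plus all
# intermediates so the factored constructor can reuse it.
#
# count_basis = "loci" follows the stated procedure literally: numAlleles = 2n
# and a row is inverted when its sum exceeds n (the locus count). With n >= m
# this never triggers; "individuals" instead uses numAlleles = 2m and the
# dimensionally natural minor-allele threshold row sum > m/2.
wj_prepare <- function(G, count_basis = c("loci", "individuals")) {
  count_basis <- match.arg(count_basis)
  check_coding(G, "binary")
  n <- G$n
  m <- G$m
  num_alleles <- if (count_basis == "loci") 2 * n else 2 * m
  threshold <- if (count_basis == "loci") n else m / 2
  sum_variants <- Matrix::rowSums(G$values)
  invert <- which(sum_variants > threshold)
  Gi <- G$values
  if (length(invert)) {
    Gd <- as.matrix(Gi)
    Gd[invert, ] <- 1 - Gd[invert, ]
    Gi <- methods::as(methods::as(Matrix::Matrix(Gd, sparse = TRUE),
                                  "generalMatrix"), "CsparseMatrix")
  }
  s <- Matrix::rowSums(Gi) # recomputed on the inverted matrix
  total_pairs <- s * (s - 1) / 2
  weights <- ifelse(total_pairs > 0,
                    num_alleles * (num_alleles - 1) / total_pairs, 0)
  list(G = Gi, numAlleles = num_alleles, sumVariants = sum_variants,
       totalPairs = total_pairs, weights = weights, invertedRows = invert,
       count_basis = count_basis)
}

#' @rdname similarity
#' @param count_basis whether the weighted-Jaccard allele total
#'   \code{numAlleles} and the minor-allele inversion threshold are expressed
#'   in loci (\code{"loci"}, the default: \code{numAlleles = 2n}, invert rows
#'   whose sum strictly exceeds \eqn{n}) or individuals
#'   (\code{numAlleles = 2m}, invert rows whose sum exceeds \eqn{m/2}).
#' @return \code{weighted_jaccard_matrix}: a list with the \eqn{m \times m}
#'   similarity in \code{matrix} and the intermediates (\code{numAlleles},
#'   \code{sumVariants}, \code{totalPairs}, \code{weights},
#'   \code{invertedRows}). The similarity is
#'   \eqn{\frac{1}{4n} G^\top \mathrm{diag}(weights)\, G} on the
#'   minor-allele-inverted matrix, with per-locus weight
#'   \eqn{numAlleles(numAlleles-1)/totalPairs}, \eqn{totalPairs = s(s-1)/2}
#'   recomputed after inversion, and weight 0 where a locus has fewer than two
#'   carriers (such loci carry no pairwise-sharing information).
#' @export
weighted_jaccard_matrix <- function(G, count_basis = c("loci", "individuals")) {
  G <- as_genotype_matrix(G)
  prep <- wj_prepare(G, count_basis)
  Gd <- as.matrix(prep$G)
  M <- crossprod(Gd, prep$weights * Gd) / (4 * G$n)
  list(matrix = structure(sym(M), kind = "weighted_jaccard"),
       intermediates = prep[c("numAlleles", "sumVariants", "totalPairs",
                              "weights", "invertedRows", "count_basis")])
}

#' @rdname similarity
#' @param robust if \code{TRUE} (default) the robust GRM
#'   \eqn{C^\top C / \sum_i 2p_i(1-p_i)}; otherwise the non-robust GRM
#'   \eqn{\frac{1}{n} C^\top \mathrm{diag}(1/q)\, C}, where \eqn{p} are half
#'   row means, \eqn{q_i = 2p_i(1-p_i)} and \eqn{C} is \eqn{G} with \eqn{2p_i}
#'   subtracted from row \eqn{i}. Monomorphic loci (\eqn{q_i = 0}) contribute
#'   zero to the non-robust flavor instead of an infinite weight; their
#'   centered rows are zero anyway whenever all entries are equal.
#' @return \code{grm}: a list with the similarity in \code{matrix} and
#'   intermediates \code{p}, \code{qvec}, \code{ssum}.
#' @export
grm <- function(G, robust = TRUE) {
  G <- as_genotype_matrix(G)
  Gd <- as.matrix(G$values)
  p <- rowMeans(Gd) / 2
  qvec <- 2 * p * (1 - p)
  ssum <- sum(qvec)
  C <- Gd - 2 * p # recycles down columns: subtracts 2p_i from row i
  if (robust) {
    if (ssum <= 0) stop("robust GRM undefined: all loci are monomorphic",
                        call. = FALSE)
    M <- crossprod(C) / ssum
    kind <- "grm_robust"
  } else {
    winv <- ifelse(qvec > 0, 1 / qvec, 0)
    M <- crossprod(C * sqrt(winv)) / G$n
    kind <- "grm_nonrobust"
  }
  list(matrix = structure(sym(M), kind = kind),
       intermediates = list(p = p, qvec = qvec, ssum = ssum))
}

#' Seeded random search for a non-PSD exact Jaccard matrix
#'
#' Scans seeded random binary matrices of varied shape and density for one
#' whose exact Jaccard matrix has a genuinely negative eigenvalue (below
#' \code{-tol_rel} times the spectral radius, so floating-point noise around
#' zero is not counted). The binary Jaccard similarity coincides with the
#' min-max (Tanimoto) kernel, which is positive semidefinite, so the search
#' is expected to come back empty; it is provided so the claim can be probed
#' empirically rather than assumed.
#'
#' @param n_trials number of random matrices to scan.
#' @param seed integer seed.
#' @param tol_rel relative threshold separating a true negative eigenvalue
#'   from rounding noise.
#' @return list with \code{found} (logical), \code{min_eigenvalue} (most
#'   negative relative eigenvalue seen), and, when found, the offending
#'   \code{genotypes}.
#' @export
find_non_psd_jaccard <- function(n_trials = 500L, seed = 1L,
                                 tol_rel = 1e-8) {
  worst <- 0
  hit <- NULL
  for (t in seq_len(n_trials)) {
    dims <- with_seed(seed + t, {
      list(n = sample(2:40, 1L), m = sample(3:30, 1L),
           pi = stats::runif(1L, 0.05, 0.95))
    })
    G <- sim_binary(dims$n, dims$m, dims$pi, seed = seed + 100000L + t)
    J <- jaccard_matrix(G)
    ev <- eigen(J, symmetric = TRUE, only.values = TRUE)$values
    rad <- max(abs(ev), 1e-300)
    rel <- min(ev) / rad
    if (rel < worst) {
      worst <- rel
      if (rel < -tol_rel) hit <- G
    }
  }
  list(found = !is.null(hit), min_eigenvalue = worst, genotypes = hit)
}
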
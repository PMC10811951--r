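#' Factored operator for a named similarity
#'
#' Dispatch helper mapping a similarity name to its factored-operator
#' constructor. The exact Jaccard matrix is not decomposable and is refused
#' here (see \code{\link{factor_approx_jaccard}}).
#'
#' @param G a \code{\link{genotype_matrix}}.
#' @param kind one of \code{"covariance"}, \code{"approx_jaccard"},
#'   \code{"weighted_jaccard"}, \code{"grm_robust"}, \code{"grm_nonrobust"}.
#' @inheritParams weighted_jaccard_matrix
#' @return a \code{\link{factored_operator}}.
#' @export
similarity_operator <- function(G, kind = c("covariance", "approx_jaccard",
                                            "weighted_jaccard", "grm_robust",
                                            "grm_nonrobust"),
                                count_basis = c("loci", "individuals")) {
  kind <- match.arg(kind)
  switch(kind,
         covariance = factor_covariance(G),
         approx_jaccard = factor_approx_jaccard(G),
         weighted_jaccard = factor_weighted_jaccard(G, count_basis),
         grm_robust = factor_grm(G, robust = TRUE),
         grm_nonrobust = factor_grm(G, robust = FALSE))
}

# dense reference similarity by name (oracle path)
similarity_dense <- function(G, kind, count_basis = "loci") {
  switch(kind,
         covariance = covariance_matrix(G),
         jaccard = jaccard_matrix(G),
         approx_jaccard = approx_jaccard_matrix(G),
         weighted_jaccard = weighted_jaccard_matrix(G, count_basis)$matrix,
         grm_robust = grm(G, robust = TRUE)$matrix,
         grm_nonrobust = grm(G, robust = FALSE)$matrix,
         stop("unknown similarity kind: ", kind, call. = FALSE))
}

#' Principal components of a genomic similarity matrix
#'
#' End-to-end entry point: picks the similarity, routes to the fast factored
#' randomized SVD (default), a dense eigendecomposition of the materialised
#' similarity (oracle-sized inputs only), or the power method (leading
#' eigenvector). The exact Jaccard matrix has no Gram factorization, so
#' \code{kind = "jaccard"} is forced onto the dense path with a warning;
#' use \code{kind = "approx_jaccard"} for the scalable surrogate.
#'
#' @param G a \code{\link{genotype_matrix}} (or coercible).
#' @param kind similarity name; as \code{\link{similarity_operator}} plus
#'   \code{"jaccard"} (dense only).
#' @param k number of components.
#' @param q power exponent (default \eqn{2k}).
#' @param seed integer seed.
#' @param method \code{"fast"}, \code{"dense"}, or \code{"power"}.
#' @inheritParams weighted_jaccard_matrix
#' @param unsafe disable the k validity-range check.
#' @return an \code{eigen_result} (see \code{\link{randomized_svd}}).
#' @examples
#' G <- sim_binary(300, 40, pi = 0.1, seed = 3)
#' res <- genotype_pca(G, "approx_jaccard", k = 2, seed = 3)
#' res$values
#' @export
genotype_pca <- function(G, kind = c("covariance", "approx_jaccard",
                                     "weighted_jaccard", "grm_robust",
                                     "grm_nonrobust", "jaccard"),
                         k = 2L, q = 2L * k, seed = 1L,
                         method = c("fast", "dense", "power"),
                         count_basis = c("loci", "individuals"),
                         unsafe = FALSE) {
  kind <- match.arg(kind)
  method <- match.arg(method)
  G <- as_genotype_matrix(G)
  if (kind == "jaccard" && method != "dense") {
    warning("the exact Jaccard matrix admits no X'X factorization; ",
            "falling back to the dense eigendecomposition")
    method <- "dense"
  }
  if (method == "fast") {
    F <- similarity_operator(G, kind, count_basis)
    return(fast_eigenvectors(F, k = k, q = q, seed = seed, unsafe = unsafe))
  }
  if (method == "dense") {
    S <- similarity_dense(G, kind, match.arg(count_basis))
    ev <- eigen(S, symmetric = TRUE)
    U <- ev$vectors[, seq_len(k), drop = FALSE]
    for (j in seq_len(k)) {
      i0 <- which.max(abs(U[, j]))
      if (U[i0, j] < 0) U[, j] <- -U[, j]
    }
    return(structure(list(vectors = U, values = ev$values[seq_len(k)],
                          singular_values = sqrt(pmax(ev$values[seq_len(k)], 0)),
                          left = NULL, k = k, q = NA_integer_, seed = seed,
                          method = "dense",
                          degenerate = all(ev$values[seq_len(k)] <= 0)),
                     class = "eigen_result"))
  }
  # power method on the implied similarity, leading eigenvector only
  if (k != 1L) stop("method = 'power' computes the leading eigenvector only ",
                    "(k = 1)", call. = FALSE)
  F <- similarity_operator(G, if (kind == "jaccard") "approx_jaccard" else kind,
                           count_basis)
  pm <- power_method(function(y) op_rmatvec(F, op_matvec(F, y)),
                     dim = G$m, iters = 100L, seed = seed)
  U <- matrix(pm$vector, ncol = 1L)
  i0 <- which.max(abs(U[, 1L]))
  if (U[i0, 1L] < 0) U[, 1L] <- -U[, 1L]
  structure(list(vectors = U, values = pm$value,
                 singular_values = sqrt(max(pm$value, 0)), left = NULL,
                 k = 1L, q = NA_integer_, seed = seed, method = "power",
                 degenerate = isTRUE(pm$degenerate)),
            class = "eigen_result")
}
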
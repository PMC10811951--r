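#' Simulate a sparse binary genotype matrix
#'
#' Draws every entry of an \eqn{n \times m} matrix independently as
#' Bernoulli(\code{pi}), the non-zero entries acting as non-reference alleles.
#' This is the simulation model used throughout the numerical experiments:
#' no linkage, row or column structure is imposed, and all-zero rows or
#' columns are retained (downstream code must tolerate them).
#'
#' The matrix is materialised sparsely: the total number of ones is drawn
#' from Binomial(\eqn{nm}, \code{pi}) and positions are sampled uniformly
#' without replacement, which is distributionally identical to entrywise
#' i.i.d. Bernoulli draws but never allocates a dense \eqn{n \times m} block.
#'
#' @param n number of loci (rows), >= 1.
#' @param m number of individuals (columns), >= 1.
#' @param pi probability in \[0,1\] that an entry equals one.
#' @param seed integer seed; the same seed reproduces the matrix bit for bit.
#' @return a \code{\link{genotype_matrix}} with \code{coding = "binary"}.
#' @examples
#' G <- sim_binary(100, 20, pi = 0.1, seed = 7)
#' mean(as.matrix(G) == 1)
#' @export
sim_binary <- function(n, m, pi, seed) {
  stopifnot(n >= 1, m >= 1)
  if (!is.numeric(pi) || length(pi) != 1L || is.na(pi) || pi < 0 || pi > 1) {
    stop("pi must be a single probability in [0, 1]", call. = FALSE)
  }
  N <- as.double(n) * as.double(m)
  if (N >= 2^31) stop("n*m too large for the position sampler", call. = FALSE)
  idx <- with_seed(seed, {
    nnz <- stats::rbinom(1L, size = as.integer(N), prob = pi)
    sort(sample.int(as.integer(N), nnz))
  })
  # linear index (column-major) -> (row, col)
  i <- ((idx - 1L) %% n) + 1L
  j <- ((idx - 1L) %/% n) + 1L
  V <- Matrix::sparseMatrix(i = i, j = j, x = rep(1, length(i)),
                            dims = c(n, m))
  genotype_matrix(V, coding = "binary")
}

#' Simulate a dosage genotype matrix
#'
#' Per-locus allele frequencies \eqn{p_i} are drawn uniformly in
#' \[\code{maf_low}, \code{maf_high}\] and each individual's genotype at locus
#' \eqn{i} is Binomial(2, \eqn{p_i}), i.e. an unphased biallelic dosage in
#' \{0,1,2\}. Intended as input for the covariance and GRM similarities.
#'
#' @param n,m loci and individual counts.
#' @param maf_low,maf_high allele-frequency range, 0 < low <= high <= 0.5.
#' @param seed integer seed.
#' @return a \code{\link{genotype_matrix}} with \code{coding = "dosage012"}.
#' @export
sim_dosage <- function(n, m, maf_low = 0.05, maf_high = 0.5, seed = 1L) {
  stopifnot(n >= 1, m >= 1)
  if (!(maf_low > 0 && maf_low <= maf_high && maf_high <= 0.5)) {
    stop("need 0 < maf_low <= maf_high <= 0.5", call. = FALSE)
  }
  vals <- with_seed(seed, {
    p <- stats::runif(n, maf_low, maf_high)
    matrix(stats::rbinom(n * m, size = 2L, prob = rep(p, times = m)), n, m)
  })
  genotype_matrix(vals, coding = "dosage012")
}

#' Simulate stratified populations (Balding-Nichols model)
#'
#' Emulates population structure: ancestral allele frequencies are uniform in
#' \[0.05, 0.5\] and each population's frequency is a Beta draw centred on the
#' ancestral value with dispersion controlled by \code{divergence} (the Fst-like
#' parameter \eqn{F} of the Balding-Nichols model: shape parameters
#' \eqn{p(1-F)/F} and \eqn{(1-p)(1-F)/F}). Genotypes are Binomial(2, freq)
#' dosages. This is a test fixture emulating stratified cohorts, not a claim
#' of realism (no linkage disequilibrium, no admixture).
#'
#' @param n loci count.
#' @param m_per_pop individuals per population.
#' @param n_pops number of populations (>= 1).
#' @param divergence Balding-Nichols divergence F in (0, 1).
#' @param seed integer seed.
#' @return list with \code{genotypes} (a dosage \code{genotype_matrix}) and
#'   \code{populations} (factor of length \code{m_per_pop * n_pops}).
#' @export
sim_stratified <- function(n, m_per_pop, n_pops = 2L, divergence = 0.1,
                           seed = 1L) {
  stopifnot(n >= 1, m_per_pop >= 1, n_pops >= 1)
  if (!(divergence > 0 && divergence < 1)) {
    stop("divergence must lie in (0, 1)", call. = FALSE)
  }
  m <- m_per_pop * n_pops
  vals <- with_seed(seed, {
    p0 <- stats::runif(n, 0.05, 0.5)
    out <- matrix(0L, n, m)
    for (k in seq_len(n_pops)) {
      pk <- stats::rbeta(n,
                         shape1 = p0 * (1 - divergence) / divergence,
                         shape2 = (1 - p0) * (1 - divergence) / divergence)
      cols <- ((k - 1L) * m_per_pop + 1L):(k * m_per_pop)
      out[, cols] <- stats::rbinom(n * m_per_pop, size = 2L,
                                   prob = rep(pk, times = m_per_pop))
    }
    out
  })
  list(genotypes = genotype_matrix(vals, coding = "dosage012"),
       populations = factor(rep(paste0("pop", seq_len(n_pops)),
                                each = m_per_pop)))
}
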
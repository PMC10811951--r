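#' Sparse loci-by-individuals genotype matrix
#'
#' Light container for a genomic input matrix \eqn{G \in R^{n \times m}} with
#' \eqn{n} loci (rows) and \eqn{m} individuals (columns), stored in sparse
#' column-compressed form. Two codings are supported: \code{"binary"}
#' (presence/absence of a non-reference allele, values in \{0,1\}; required by
#' the Jaccard-family similarities) and \code{"dosage012"} (alternate-allele
#' counts in \{0,1,2\}; the usual input for covariance and GRM).
#'
#' @param values a matrix-like object (base matrix or \pkg{Matrix} sparse
#'   matrix) with non-negative integer entries.
#' @param coding \code{"binary"} or \code{"dosage012"}. If \code{NULL}, the
#'   coding is inferred: \code{"binary"} iff all values are in \{0,1\},
#'   otherwise \code{"dosage012"}.
#' @param allow_empty permit zero rows (used by the VCF reader when every
#'   record is skipped); the default enforces \eqn{n \ge 1}, \eqn{m \ge 1}.
#' @return an object of class \code{"genotype_matrix"}: a list with elements
#'   \code{values} (a \code{dgCMatrix}), \code{coding}, \code{n}, \code{m}.
#' @examples
#' G <- genotype_matrix(rbind(c(1, 0, 1), c(0, 1, 1)))
#' G$coding
#' dim(G)
#' @export
genotype_matrix <- function(values, coding = NULL, allow_empty = FALSE) {
  V <- methods::as(methods::as(methods::as(Matrix::Matrix(values, sparse = TRUE),
                                           "dMatrix"),
                               "generalMatrix"),
                   "CsparseMatrix")
  n <- nrow(V)
  m <- ncol(V)
  if (!allow_empty && (n < 1L || m < 1L)) {
    stop("genotype matrix must have at least one locus and one individual",
         call. = FALSE)
  }
  x <- V@x
  if (length(x) && (any(!is.finite(x)) || any(x < 0) || any(x != round(x)))) {
    stop("genotype values must be non-negative integers", call. = FALSE)
  }
  if (is.null(coding)) {
    coding <- if (!length(x) || all(x <= 1)) "binary" else "dosage012"
  }
  coding <- match.arg(coding, c("binary", "dosage012"))
  limit <- if (coding == "binary") 1 else 2
  if (length(x) && any(x > limit)) {
    stop(sprintf("value %g is not representable under coding '%s'",
                 max(x), coding), call. = FALSE)
  }
  structure(list(values = V, coding = coding, n = n, m = m),
            class = "genotype_matrix")
}

#' Coerce to a genotype matrix
#'
#' @param x a \code{genotype_matrix}, base matrix, or \pkg{Matrix} matrix.
#' @param coding optional coding override (validated).
#' @return a \code{genotype_matrix}.
#' @export
as_genotype_matrix <- function(x, coding = NULL) {
  if (inherits(x, "genotype_matrix")) {
    if (!is.null(coding) && !identical(coding, x$coding)) {
      return(genotype_matrix(x$values, coding = coding))
    }
    return(x)
  }
  genotype_matrix(x, coding = coding)
}

#' @exportS3Method
dim.genotype_matrix <- function(x) c(x$n, x$m)

#' @exportS3Method base::print
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d loci x %d individuals, coding=%s, nnz=%d\n",
              x$n, x$m, x$coding, length(x$values@x)))
  invisible(x)
}

#' @exportS3Method base::as.matrix
as.matrix.genotype_matrix <- function(x, ...) as.matrix(x$values)

# internal: stop unless G carries the coding a similarity requires
check_coding <- function(G, required) {
  if (!identical(G$coding, required)) {
    stop(sprintf("this similarity requires coding '%s' (got '%s')",
                 required, G$coding), call. = FALSE)
  }
  invisible(G)
}

# internal: run expr under a private RNG stream seeded with `seed`,
# restoring the caller's global RNG state afterwards
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed must be a single finite integer", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
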
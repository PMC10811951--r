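#' @name bounds
#' @title Davis-Kahan error bounds for the Jaccard approximation
#'
#' @description
#' The approximate Jaccard matrix \eqn{\hat J} trades accuracy for a Gram
#' structure; these functions quantify the trade. For two symmetric matrices
#' with sorted eigenvalues \eqn{\lambda_1 \ge \lambda_2 \ge \dots} and
#' \eqn{\hat\lambda_1 \ge \hat\lambda_2 \ge \dots}, the Davis-Kahan
#' \eqn{\sin\theta} theorem chains as
#' \deqn{\min_{\epsilon = \pm 1} \|u_1 - \epsilon \hat u_1\|_2
#'   \le \sqrt{2}\,|\sin\angle(u_1, \hat u_1)|
#'   \le 2\sqrt{2}\, \frac{\|J - \hat J\|_{op}}
#'        {\max(\lambda_1 - \lambda_2,\ \hat\lambda_1 - \hat\lambda_2)}.}
#' The first inequality is the (a-posteriori) angle bound, the second the
#' matrix bound, computable a priori: the operator norm may be relaxed to the
#' Frobenius norm, and the eigenvalue gap can be estimated without any dense
#' eigendecomposition via the power method or bounded via Gershgorin discs.
NULL

unitize_check <- function(u, tol = 1e-8) {
  nu <- sqrt(sum(u^2))
  if (abs(nu - 1) > tol) stop("input vector is not unit norm", call. = FALSE)
  u
}

#' @rdname bounds
#' @param u,v unit vectors of equal length.
#' @return \code{l2_distance_up_to_sign}: \eqn{\min(\|u-v\|_2, \|u+v\|_2)},
#'   the L2 distance modulo the sign ambiguity of eigenvectors.
#' @export
l2_distance_up_to_sign <- function(u, v) {
  unitize_check(u)
  unitize_check(v)
  min(sqrt(sum((u - v)^2)), sqrt(sum((u + v)^2)))
}

#' @rdname bounds
#' @return \code{angle_bound}: \eqn{\sqrt{2}\,|\sin\angle(u,v)|}, an upper
#'   bound on the sign-minimised L2 distance.
#' @export
angle_bound <- function(u, v) {
  unitize_check(u)
  unitize_check(v)
  cosang <- min(abs(sum(u * v)), 1)
  sqrt(2) * sqrt(1 - cosang^2)
}

#' @rdname bounds
#' @param A symmetric matrix.
#' @return \code{gershgorin_bounds}: data frame with one disc per row
#'   (\code{center} = diagonal entry, \code{radius} = off-diagonal absolute
#'   row sum, \code{lower}, \code{upper}); every eigenvalue of \code{A} lies
#'   in the union of the intervals.
#' @export
gershgorin_bounds <- function(A) {
  A <- as.matrix(A)
  stopifnot(nrow(A) == ncol(A))
  center <- diag(A)
  radius <- rowSums(abs(A)) - abs(center)
  data.frame(center = center, radius = radius,
             lower = center - radius, upper = center + radius)
}

# a-priori lower bound on lambda_1 - lambda_2 from Gershgorin discs.
# If the interval union splits so that its topmost connected component
# contains exactly one disc, that component holds exactly lambda_1 and the
# rest of the union holds lambda_2, giving gap >= lower(top) - upper(rest).
# Otherwise the discs cannot separate the top two eigenvalues: NA (vacuous).
gershgorin_gap <- function(A) {
  d <- gershgorin_bounds(A)
  o <- order(d$lower)
  lo <- d$lower[o]
  hi <- d$upper[o]
  # merge into connected components
  comp_lo <- lo[1]
  comp_hi <- hi[1]
  sizes <- 1L
  for (i in seq_along(lo)[-1]) {
    j <- length(comp_lo)
    if (lo[i] <= comp_hi[j]) {
      comp_hi[j] <- max(comp_hi[j], hi[i])
      sizes[j] <- sizes[j] + 1L
    } else {
      comp_lo <- c(comp_lo, lo[i])
      comp_hi <- c(comp_hi, hi[i])
      sizes <- c(sizes, 1L)
    }
  }
  nc <- length(comp_lo)
  if (nc < 2L || sizes[nc] != 1L) return(NA_real_)
  comp_lo[nc] - comp_hi[nc - 1L]
}

# eigengap lambda_order - lambda_{order+1} of a symmetric matrix, by the
# requested estimation method
eigen_gap <- function(A, order = 1L, method = c("dense", "power", "gershgorin"),
                      iters = 100L, seed = 1L) {
  method <- match.arg(method)
  A <- as.matrix(A)
  d <- nrow(A)
  if (order + 1L > d) return(NA_real_)
  if (method == "dense") {
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    return(ev[order] - ev[order + 1L])
  }
  if (method == "gershgorin") {
    if (order != 1L) {
      stop("Gershgorin gap estimation is only available for order 1",
           call. = FALSE)
    }
    return(gershgorin_gap(A))
  }
  # power method with repeated deflation A <- A - lambda u u'
  lam <- numeric(order + 1L)
  Ad <- A
  for (i in seq_len(order + 1L)) {
    pm <- power_method(function(y) as.numeric(Ad %*% y), dim = d,
                       iters = iters, seed = seed + i)
    lam[i] <- pm$value
    Ad <- Ad - pm$value * tcrossprod(pm$vector)
  }
  lam[order] - lam[order + 1L]
}

#' @rdname bounds
#' @param J,Jhat symmetric matrices of equal dimension (the exact and
#'   approximate similarity).
#' @param norm \code{"frobenius"} (default; relaxes the operator norm via
#'   norm equivalence, cheap and always an upper bound) or \code{"operator"}
#'   (spectral norm, computed densely).
#' @param gap_method how the eigengaps entering the denominator are obtained:
#'   \code{"dense"} eigensolver, \code{"power"} (power method plus deflation,
#'   100 iterations per stage), or \code{"gershgorin"} (fully a-priori disc
#'   arithmetic; may fail to separate the top two eigenvalues, in which case
#'   the bound is vacuous).
#' @param order eigenvector index: 1 (default) is the stated theorem; for
#'   \eqn{i > 1} the consecutive-gap generalisation
#'   \eqn{\max(\lambda_i - \lambda_{i+1}, \hat\lambda_i - \hat\lambda_{i+1})}
#'   is used (an explicit extrapolation, opt-in only).
#' @param seed seed for the power-method start vectors.
#' @return \code{matrix_bound}: the scalar bound
#'   \eqn{2\sqrt{2}\|J-\hat J\| / gap}, with attribute \code{vacuous = TRUE}
#'   and value \code{Inf} when the computed gap is non-positive or
#'   unavailable (degenerate spectra are legitimate inputs, not errors).
#' @export
matrix_bound <- function(J, Jhat, norm = c("frobenius", "operator"),
                         gap_method = c("dense", "power", "gershgorin"),
                         order = 1L, seed = 1L) {
  norm <- match.arg(norm)
  gap_method <- match.arg(gap_method)
  J <- as.matrix(J)
  Jhat <- as.matrix(Jhat)
  stopifnot(all(dim(J) == dim(Jhat)), nrow(J) == ncol(J))
  D <- J - Jhat
  nrm <- if (norm == "frobenius") norm(D, "F") else norm(D, "2")
  g1 <- eigen_gap(J, order, gap_method, seed = seed)
  g2 <- eigen_gap(Jhat, order, gap_method, seed = seed + 1000L)
  gap <- suppressWarnings(max(g1, g2, na.rm = TRUE))
  if (!is.finite(gap) || gap <= 0) {
    return(structure(Inf, vacuous = TRUE, gap = gap))
  }
  structure(2 * sqrt(2) * nrm / gap, vacuous = FALSE, gap = gap)
}

#' Bound report for the Jaccard approximation on a genotype matrix
#'
#' Computes the exact Jaccard matrix \eqn{J} and its approximation
#' \eqn{\hat J} for a binary genotype matrix, their dense eigenpairs, and for
#' each requested eigenvector order the measured sign-minimised L2 distance,
#' the angle bound, and the matrix bound. The matrix-bound column uses the
#' first eigengap \eqn{\max(\lambda_1-\lambda_2, \hat\lambda_1-\hat\lambda_2)}
#' for every order: it depends only on the two matrices, not on which
#' eigenvector is examined, and is therefore constant across the report.
#' Order-specific gaps are available through \code{\link{matrix_bound}}.
#'
#' Guarded to oracle-sized inputs, since it necessarily densifies both
#' similarity matrices.
#'
#' @param G binary \code{\link{genotype_matrix}}.
#' @param orders integer vector of eigenvector indices (default 1).
#' @param norm,gap_method passed to \code{\link{matrix_bound}}.
#' @param max_elements refusal threshold on \eqn{n \times m}.
#' @return data frame with columns \code{order}, \code{l2_measured},
#'   \code{angle_bound}, \code{matrix_bound}, \code{gap}, \code{norm},
#'   \code{gap_method}, \code{vacuous}.
#' @export
jaccard_bound_report <- function(G, orders = 1L,
                                 norm = c("frobenius", "operator"),
                                 gap_method = c("dense", "power", "gershgorin"),
                                 max_elements = 2e7) {
  norm <- match.arg(norm)
  gap_method <- match.arg(gap_method)
  G <- as_genotype_matrix(G)
  check_coding(G, "binary")
  if (as.double(G$n) * G$m > max_elements) {
    stop("refusing: input too large for the dense Jaccard oracle",
         call. = FALSE)
  }
  orders <- sort(unique(as.integer(orders)))
  stopifnot(all(orders >= 1), max(orders) < G$m)
  J <- jaccard_matrix(G)
  Jhat <- approx_jaccard_matrix(G)
  eJ <- eigen(J, symmetric = TRUE)
  eH <- eigen(Jhat, symmetric = TRUE)
  mb <- matrix_bound(J, Jhat, norm = norm, gap_method = gap_method, order = 1L)
  out <- lapply(orders, function(i) {
    u <- eJ$vectors[, i] / sqrt(sum(eJ$vectors[, i]^2))
    v <- eH$vectors[, i] / sqrt(sum(eH$vectors[, i]^2))
    data.frame(order = i,
               l2_measured = l2_distance_up_to_sign(u, v),
               angle_bound = angle_bound(u, v),
               matrix_bound = as.numeric(mb),
               gap = as.numeric(attr(mb, "gap")),
               norm = norm, gap_method = gap_method,
               vacuous = isTRUE(attr(mb, "vacuous")))
  })
  do.call(rbind, out)
}
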
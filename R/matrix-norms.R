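## Numerically safe primitives shared by every update rule: Schatten-type
## norms, the capped column norm, and regularized fractional matrix powers.

.assertFinite <- function(x, what) {
  if (!is.numeric(x) || anyNA(x) || !all(is.finite(x)))
    stop("non-finite entries in ", what, call. = FALSE)
  invisible(TRUE)
}

.singularValues <- function(G) {
  if (length(G) == 0L || ncol(G) == 0L || nrow(G) == 0L) return(numeric(0))
  svd(G, nu = 0, nv = 0)$d
}

#' Schatten p-norm
#'
#' \eqn{\|G\|_{S_p} = (\sum_i \sigma_i^p)^{1/p}} over all
#' \eqn{\min(m, n)} singular values \eqn{\sigma_i} of \eqn{G}.
#' \code{p = 1} gives the nuclear norm, \code{p = 2} the Frobenius norm, and
#' \code{0 < p < 1} a tighter (non-convex) surrogate for the matrix rank.
#'
#' @param G A real matrix with finite entries.
#' @param p Norm exponent, a single positive number.
#' @return A non-negative scalar.
#' @examples
#' schattenNorm(diag(c(3, 4)), 1)  # nuclear norm = 7
#' schattenNorm(diag(c(3, 4)), 2)  # Frobenius norm = 5
#' @export
schattenNorm <- function(G, p) {
  G <- as.matrix(G)
  .assertFinite(G, "G")
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p <= 0)
    stop("'p' must be a single positive number", call. = FALSE)
  d <- .singularValues(G)
  if (!length(d)) return(0)
  sum(d^p)^(1 / p)
}

#' Low-rank penalty term
#'
#' The scalar \eqn{\mathrm{Tr}((G^T G)^k) = \sum_i \sigma_i(G)^{2k}}, i.e. the
#' squared k-power Schatten norm \eqn{(\|G\|_{S_p}^k)^2} under the convention
#' \eqn{p = 2k}. This is the rank surrogate attached to each cluster block of
#' the low-rank representation; \code{k = 1} reduces it to the squared
#' Frobenius norm.
#'
#' @param G A real matrix (may have zero columns, giving 0).
#' @param k Schatten exponent in (0, 1].
#' @return A non-negative scalar.
#' @export
lowRankTerm <- function(G, k) {
  G <- as.matrix(G)
  .assertFinite(G, "G")
  if (!is.numeric(k) || length(k) != 1L || !is.finite(k) || k <= 0 || k > 1)
    stop("'k' must lie in (0, 1]", call. = FALSE)
  d <- .singularValues(G)
  if (!length(d)) return(0)
  sum(d^(2 * k))
}

#' Column Euclidean norms
#'
#' @param E A real matrix.
#' @return Vector of the Euclidean norms of the columns of \code{E}.
#' @export
columnNorms <- function(E) {
  E <- as.matrix(E)
  .assertFinite(E, "E")
  sqrt(colSums(E^2))
}

#' L2,1 norm (sum of column norms)
#'
#' \eqn{\|E\|_{2,1} = \sum_j \|E_j\|_2}; induces column-wise sparsity and is
#' the standard model for sample-specific corruption.
#'
#' @param E A real matrix.
#' @return A non-negative scalar.
#' @export
l21Norm <- function(E) {
  sum(columnNorms(E))
}

#' Capped column norm
#'
#' \eqn{\sum_j \min(\|E_j\|_2, \theta)}: columns whose norm exceeds the
#' threshold \eqn{\theta} are charged the fixed cost \eqn{\theta}, which
#' removes (rather than merely shrinks) the influence of extreme outlier
#' samples. With \code{theta = Inf} this is exactly the L2,1 norm.
#'
#' @param E A real matrix.
#' @param theta Positive threshold; \code{Inf} is allowed.
#' @return A non-negative scalar, never exceeding \code{ncol(E) * theta}.
#' @export
cappedNorm <- function(E, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || is.na(theta) || theta <= 0)
    stop("'theta' must be a single positive number (Inf allowed)",
         call. = FALSE)
  sum(pmin(columnNorms(E), theta))
}

#' Regularized symmetric matrix power
#'
#' Computes \eqn{V \mathrm{diag}((\lambda + \epsilon)^q) V^T} from the
#' eigendecomposition \eqn{S = V \mathrm{diag}(\lambda) V^T}, with eigenvalues
#' clamped at zero before the ridge \eqn{\epsilon} is added. Negative
#' exponents of possibly rank-deficient PSD matrices (as needed by the
#' gradient weightings of the solver) are only defined through the ridge,
#' so \code{eps > 0} is required whenever \code{q < 0}.
#'
#' @param S A symmetric positive semi-definite matrix (symmetry is checked to
#'   a tolerance of \code{1e-8 * max(abs(S))} and the input is symmetrized
#'   before decomposition).
#' @param q Real exponent.
#' @param eps Non-negative ridge added to the (clamped) eigenvalues.
#' @return A symmetric matrix of the same dimension as \code{S}.
#' @export
symPower <- function(S, q, eps = 0) {
  S <- as.matrix(S)
  .assertFinite(S, "S")
  if (nrow(S) != ncol(S)) stop("'S' must be square", call. = FALSE)
  if (eps < 0) stop("'eps' must be >= 0", call. = FALSE)
  if (q < 0 && eps == 0)
    stop("'eps' must be > 0 for negative exponents", call. = FALSE)
  scale <- max(abs(S))
  if (scale > 0 && max(abs(S - t(S))) > 1e-8 * scale)
    stop("'S' is not symmetric within tolerance", call. = FALSE)
  S <- (S + t(S)) / 2
  eg <- eigen(S, symmetric = TRUE)
  lam <- pmax(eg$values, 0) + eps
  if (any(lam == 0) && q < 0)
    stop("zero eigenvalue with negative exponent", call. = FALSE)
  out <- eg$vectors %*% (t(eg$vectors) * lam^q)
  (out + t(out)) / 2
}
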
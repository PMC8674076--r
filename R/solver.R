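## ALM block updates. Each update has a closed form; the stationarity
## conditions are exact and are exercised directly by the test suite.

.ridgeFor <- function(lamMax, ridge) max(ridge * lamMax, 1e-12)

#' A-update of the ALM loop
#'
#' With E and the indicators fixed, the low-rank representation solves
#' \deqn{\min_A \mathrm{Tr}((A^T A)^k) + (\mu/2) \|A - B\|_F^2,}
#' where \eqn{B = X - E + Y/\mu}, through one majorize-minimize step: the
#' concave trace power is linearized at the previous iterate via
#' \eqn{H = k (A_{prev}^T A_{prev} + \epsilon I)^{k-1}} and the resulting
#' quadratic is solved exactly, \eqn{A = \mu B (2H + \mu I)^{-1}}. The
#' returned matrix satisfies the stationarity condition
#' \eqn{2AH + \mu(A - B) = 0} (H held fixed) to machine precision. For
#' \code{k = 1}, \eqn{H = I} exactly and the update is the closed form
#' \eqn{(\mu/(2+\mu)) B}.
#'
#' @param X,E,Y Data, noise and multiplier matrices (m x n).
#' @param mu Positive penalty parameter.
#' @param Aprev Previous low-rank iterate (linearization point).
#' @param k Schatten exponent in (0, 1].
#' @param ridge Relative eigenvalue ridge for the fractional power of the
#'   Gram matrix (floored at 1e-12 absolute).
#' @return The updated m x n matrix A.
#' @export
updateA <- function(X, E, Y, mu, Aprev, k, ridge = 1e-10) {
  .assertFinite(X, "X"); .assertFinite(E, "E"); .assertFinite(Y, "Y")
  if (mu <= 0) stop("'mu' must be > 0", call. = FALSE)
  B <- X - E + Y / mu
  if (k == 1) return((mu / (2 + mu)) * B)
  S <- crossprod(Aprev)
  eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  eps <- .ridgeFor(max(lam, 0), ridge)
  h <- k * (lam + eps)^(k - 1)
  V <- eg$vectors
  (mu * B) %*% V %*% (t(V) / (2 * h + mu))
}

#' Reweighting diagonal of the capped-norm IRLS step
#'
#' Entry i is \eqn{1/(2\|E_i\|_2)} when \eqn{\|E_i\|_2 < \theta} (strict
#' inequality, so a column sitting exactly at the threshold is treated as an
#' outlier) and 0 otherwise. Zero-norm columns get the capped weight
#' \code{1/(2 * epsNorm)}, the standard IRLS smoothing of the otherwise
#' singular weight.
#'
#' @param E Noise matrix.
#' @param theta Positive threshold (Inf allowed).
#' @param epsNorm Column-norm floor (default 1e-10).
#' @return Non-negative weight vector of length \code{ncol(E)}.
#' @export
updateWeights <- function(E, theta, epsNorm = 1e-10) {
  if (theta <= 0) stop("'theta' must be > 0", call. = FALSE)
  nrm <- columnNorms(E)
  ifelse(nrm < theta, 1 / (2 * pmax(nrm, epsNorm)), 0)
}

#' E-update of the ALM loop
#'
#' With A, the indicators and the weights O fixed, the noise matrix solves
#' \deqn{\min_E \lambda \mathrm{Tr}(O E^T E) + (\mu/2)\|E - F\|_F^2,}
#' where \eqn{F = X - A + Y/\mu}. Because O is diagonal this is a per-column
#' scaling, \eqn{E_j = \mu F_j / (2\lambda O_{jj} + \mu)}, satisfying the
#' stationarity condition \eqn{2\lambda E O + \mu(E - F) = 0} exactly. A
#' column flagged as outlier (weight 0) gets \eqn{E_j = F_j}: its entire
#' residual is absorbed into the noise matrix and it no longer influences the
#' low-rank fit.
#'
#' @param X,A,Y Data, low-rank and multiplier matrices.
#' @param mu Positive penalty parameter.
#' @param lambda Positive balance parameter.
#' @param weights Non-negative reweighting diagonal (from
#'   \code{\link{updateWeights}}).
#' @return The updated m x n matrix E.
#' @export
updateE <- function(X, A, Y, mu, lambda, weights) {
  if (mu <= 0 || lambda <= 0) stop("'mu' and 'lambda' must be > 0",
                                   call. = FALSE)
  if (any(weights < 0)) stop("'weights' must be >= 0", call. = FALSE)
  Fm <- X - A + Y / mu
  scale <- mu / (2 * lambda * weights + mu)
  Fm * rep(scale, each = nrow(Fm))
}

.checkLabels <- function(labels, c, n) {
  labels <- as.integer(labels)
  if (length(labels) != n || anyNA(labels) || any(labels < 1L) ||
      any(labels > c))
    stop("labels must be integers in 1..", c, " of length ", n,
         call. = FALSE)
  labels
}

## sum_i Tr((I_i A^T A I_i)^k): the partition-dependent low-rank part of the
## objective.
.partitionValue <- function(A, labels, c, k) {
  v <- 0
  for (i in seq_len(c)) {
    J <- which(labels == i)
    if (length(J)) v <- v + lowRankTerm(A[, J, drop = FALSE], k)
  }
  v
}

#' Model objective
#'
#' The value \eqn{\sum_{i=1}^{c} \mathrm{Tr}((I_i A^T A I_i)^k) + \lambda
#' \sum_j \min(\|E_j\|_2, \theta)}: the per-cluster Schatten rank surrogate
#' of the low-rank representation plus the capped column-norm of the noise.
#'
#' @param A,E Current low-rank and noise matrices.
#' @param labels Integer cluster labels in 1..clusters.
#' @param param An \linkS4class{OrlrsParam} supplying clusters, lambda,
#'   theta and k.
#' @return A non-negative scalar.
#' @export
objectiveValue <- function(A, E, labels, param) {
  labels <- .checkLabels(labels, param@clusters, ncol(A))
  .partitionValue(A, labels, param@clusters, param@k) +
    param@lambda * cappedNorm(E, param@theta)
}

## Augmented-Lagrangian merit at the (Y, mu) in force: objective plus the
## quadratic feasibility penalty. Under the sign convention of updateA /
## updateE (B and F carry +Y/mu) the completed square is
## ||A + E - X - Y/mu||^2. This is the quantity each block update provably
## decreases within an outer iteration.
.meritValue <- function(X, A, E, labels, param, Y, mu) {
  objectiveValue(A, E, labels, param) +
    (mu / 2) * sum((A + E - X - Y / mu)^2)
}
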
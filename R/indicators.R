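## Discrete indicator optimization: the "one-step" device. The indicator
## subproblem min sum_i Tr((I_i A^T A I_i)^k) over binary diagonal matrices
## summing to the identity is solved by alternating a linearization (the
## score matrix below) with an exact per-sample argmin assignment.

#' Per-sample cluster scores
#'
#' For each cluster i the linearized cost of keeping sample j in cluster i is
#' \eqn{z_{ji} = (A^T L_i A)_{jj}} with
#' \eqn{L_i = k \|A I_i\|_{S_p}^k (A I_i A^T + \epsilon I)^{(k-2)/2}}
#' (convention \eqn{p = 2k}, so the scalar prefactor is
#' \eqn{k \sqrt{\mathrm{Tr}((I_i A^T A I_i)^k)}}). Only the diagonal of
#' \eqn{A^T L_i A} is formed, through the thin SVD of the cluster's columns:
#' for \eqn{A I_i = U \Sigma V^T},
#' \deqn{z_{ji} = s_i\left[\epsilon^{q}\|A_j\|^2 + \sum_l
#'   ((\sigma_l^2+\epsilon)^{q} - \epsilon^{q}) (u_l^T A_j)^2\right],
#'   \quad q = (k-2)/2,}
#' which matches the dense m x m regularized power exactly (the ridge defines
#' the null-space contribution) without ever forming it. An empty cluster has
#' prefactor 0 and scores identically 0.
#'
#' @param A The m x n low-rank representation.
#' @param labels Current integer labels in 1..clusters.
#' @param clusters Number of clusters.
#' @param k Schatten exponent in (0, 1].
#' @param ridge Relative eigenvalue ridge (floored at 1e-12).
#' @return An n x clusters matrix of non-negative scores.
#' @export
clusterScores <- function(A, labels, clusters, k, ridge = 1e-10) {
  A <- as.matrix(A)
  n <- ncol(A)
  labels <- .checkLabels(labels, clusters, n)
  if (!any(tabulate(labels, clusters) > 0L))
    stop("all clusters are empty", call. = FALSE)
  scores <- matrix(0, n, clusters)
  a2 <- colSums(A^2)
  q <- (k - 2) / 2
  for (i in seq_len(clusters)) {
    J <- which(labels == i)
    if (!length(J)) next
    sv <- svd(A[, J, drop = FALSE])
    d <- sv$d
    s <- k * sqrt(sum(d^(2 * k)))
    if (s == 0) next
    eps <- .ridgeFor(d[1]^2, ridge)
    w <- (d^2 + eps)^q - eps^q
    W <- crossprod(sv$u, A)
    scores[, i] <- s * (eps^q * a2 + colSums(W^2 * w))
  }
  scores
}

#' Assign each sample to its minimum-score cluster
#'
#' The indicator subproblem is separable per sample once the scores are
#' fixed, so the exact minimizer sets label j to \code{argmin_i scores[j, i]}
#' with ties broken toward the lowest cluster index. The result always
#' satisfies the partition constraint (every sample in exactly one cluster).
#'
#' @param scores An n x clusters score matrix.
#' @return Integer labels of length n.
#' @export
assignLabels <- function(scores) {
  scores <- as.matrix(scores)
  .assertFinite(scores, "scores")
  max.col(-scores, ties.method = "first")
}

## Empty clusters are reseeded with the sample whose best (assigned) score is
## worst, followed by one more scores/assign pass; a handful of attempts are
## allowed before accepting a partition with fewer than 'clusters' blocks.
.reseedEmpty <- function(A, labels, clusters, k, ridge) {
  for (attempt in 1:3) {
    empty <- which(tabulate(labels, clusters) == 0L)
    if (!length(empty)) return(labels)
    sc <- clusterScores(A, labels, clusters, k, ridge)
    best <- sc[cbind(seq_along(labels), labels)]
    for (i in empty) {
      j <- which.max(best)
      labels[j] <- i
      best[j] <- -Inf
    }
    sc <- clusterScores(A, labels, clusters, k, ridge)
    labels <- assignLabels(sc)
  }
  labels
}

#' Refine the discrete cluster indicators
#'
#' Alternates \code{\link{clusterScores}} and \code{\link{assignLabels}}
#' until the labels stop changing or \code{maxInner} passes are exhausted.
#' For \code{k = 1} each pass leaves the partition objective
#' \eqn{\sum_i \mathrm{Tr}(I_i A^T A I_i)} non-increasing (it equals
#' \eqn{\|A\|_F^2} for every partition, so descent holds with equality); for
#' \code{k < 1} descent is empirical and is monitored: if the tracked value
#' ever increases the loop aborts and returns the best labels seen.
#'
#' @param A The m x n low-rank representation.
#' @param labels Starting labels (a valid partition).
#' @param clusters Number of clusters.
#' @param k Schatten exponent in (0, 1].
#' @param ridge Relative eigenvalue ridge.
#' @param maxInner Maximum number of scores/assign passes; 0 returns the
#'   input unchanged.
#' @return Integer labels of length \code{ncol(A)}.
#' @export
updateIndicators <- function(A, labels, clusters, k, ridge = 1e-10,
                             maxInner = 30) {
  labels <- .checkLabels(labels, clusters, ncol(A))
  if (maxInner <= 0) return(labels)
  cur <- labels
  bestVal <- .partitionValue(A, cur, clusters, k)
  best <- cur
  for (pass in seq_len(maxInner)) {
    sc <- clusterScores(A, cur, clusters, k, ridge)
    nxt <- assignLabels(sc)
    nxt <- .reseedEmpty(A, nxt, clusters, k, ridge)
    val <- .partitionValue(A, nxt, clusters, k)
    if (k < 1 && val > bestVal * (1 + 1e-12) + 1e-15) return(best)
    if (val <= bestVal) {
      bestVal <- val
      best <- nxt
    }
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}
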
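## External clustering validity: accuracy under the optimal one-to-one label
## mapping, and normalized mutual information.

.checkLabelPair <- function(truth, pred) {
  if (length(truth) != length(pred))
    stop("label vectors must have equal length", call. = FALSE)
  if (length(truth) < 1L) stop("empty label vectors", call. = FALSE)
  if (anyNA(truth) || anyNA(pred))
    stop("labels must not contain NA", call. = FALSE)
  list(truth = as.integer(factor(truth)), pred = as.integer(factor(pred)))
}

## Minimum-cost linear sum assignment (square cost matrix) by the shortest
## augmenting path algorithm, O(n^3). Returns assign[i] = column matched to
## row i. No installed package provides this primitive.
.lapSolve <- function(cost) {
  n <- nrow(cost)
  stopifnot(ncol(cost) == n)
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)           # p[j+1]: row assigned to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assign[p[j + 1]] <- j
  assign
}

#' Clustering accuracy under the optimal label mapping
#'
#' \deqn{ACC = \max_{map} \frac{1}{n} \sum_i \phi(T_i, map(N_i)),}
#' the fraction of samples whose predicted label matches the truth under the
#' best one-to-one mapping between predicted and true cluster names,
#' computed as a maximum-weight assignment on the contingency table
#' (rectangular tables are padded with zero-weight dummies, so the predicted
#' cluster count may differ from the true one). Invariant to any relabeling
#' of either partition.
#'
#' @param truth,pred Label vectors of equal length (any atomic type; treated
#'   as categorical).
#' @return A scalar in [0, 1].
#' @examples
#' clusteringAccuracy(c(0, 0, 1, 1), c(1, 1, 0, 0))  # 1
#' @export
clusteringAccuracy <- function(truth, pred) {
  lp <- .checkLabelPair(truth, pred)
  tab <- table(lp$truth, lp$pred)
  d <- max(dim(tab))
  w <- matrix(0, d, d)
  w[seq_len(nrow(tab)), seq_len(ncol(tab))] <- tab
  assign <- .lapSolve(max(w) - w)
  matched <- sum(w[cbind(seq_len(d), assign)])
  matched / length(lp$truth)
}

#' Normalized mutual information between two partitions
#'
#' \deqn{NMI = \frac{M(S, C)}{(H(S) + H(C))/2},} with \eqn{M} the mutual
#' information of the two partitions and \eqn{H} their entropies (natural
#' logarithm; the ratio is base-invariant). Equals 1 iff the partitions are
#' identical up to relabeling. Degenerate single-class partitions have zero
#' entropy: the value is defined as 1 when both partitions are single-class
#' (they are then identical) and 0 when only one of them is.
#'
#' @inheritParams clusteringAccuracy
#' @return A scalar in [0, 1].
#' @export
nmi <- function(truth, pred) {
  lp <- .checkLabelPair(truth, pred)
  n <- length(lp$truth)
  tab <- table(lp$truth, lp$pred) / n
  pi <- rowSums(tab)
  pj <- colSums(tab)
  hS <- -sum(ifelse(pi > 0, pi * log(pi), 0))
  hC <- -sum(ifelse(pj > 0, pj * log(pj), 0))
  if (hS == 0 && hC == 0) return(1)
  if (hS == 0 || hC == 0) return(0)
  outer_p <- outer(pi, pj)
  pos <- tab > 0
  mi <- sum(tab[pos] * log(tab[pos] / outer_p[pos]))
  val <- mi / ((hS + hC) / 2)
  min(max(val, 0), 1)
}
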
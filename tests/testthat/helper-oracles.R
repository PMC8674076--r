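# Independent oracles used across tests. These deliberately avoid the
# package's own code paths: definitional formulas, dense constructions and
# exhaustive enumeration.

# Definitional Schatten sum from a directly-called decomposition.
oracleSchattenSum <- function(G, pow) {
  d <- svd(G, nu = 0, nv = 0)$d
  sum(d^pow)
}

# Exhaustive minimum of the separable indicator objective: enumerate all
# c^n assignments of samples to clusters and return the minimal total
# score sum(scores[j, l_j]).
oracleBestAssignmentValue <- function(scores) {
  n <- nrow(scores)
  c <- ncol(scores)
  grid <- as.matrix(expand.grid(rep(list(seq_len(c)), n)))
  best <- Inf
  for (r in seq_len(nrow(grid))) {
    val <- sum(scores[cbind(seq_len(n), grid[r, ])])
    if (val < best) best <- val
  }
  best
}

# Brute-force clustering accuracy: maximize the matched count over every
# one-to-one mapping of predicted cluster names onto true cluster names
# (injective in the direction that makes sense for the table shape).
oracleAccuracy <- function(truth, pred) {
  truth <- as.integer(factor(truth))
  pred <- as.integer(factor(pred))
  tl <- sort(unique(truth))
  pl <- sort(unique(pred))
  k <- max(length(tl), length(pl))
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    out
  }
  slots <- seq_len(k)
  best <- 0
  for (pm in perms(slots)) {
    # pm maps padded predicted slot -> padded true slot
    mapped <- pm[match(pred, pl)]
    best <- max(best, sum(mapped == match(truth, tl)))
  }
  best / length(truth)
}

# Direct-formula NMI from the contingency table (natural log).
oracleNmi <- function(truth, pred) {
  n <- length(truth)
  tab <- table(truth, pred) / n
  pi <- rowSums(tab)
  pj <- colSums(tab)
  h <- function(p) -sum(p[p > 0] * log(p[p > 0]))
  mi <- 0
  for (i in seq_along(pi)) for (j in seq_along(pj))
    if (tab[i, j] > 0)
      mi <- mi + tab[i, j] * log(tab[i, j] / (pi[i] * pj[j]))
  unname(mi / ((h(pi) + h(pj)) / 2))
}

# Fixture used by the indicator and solver tests: two or three exactly
# orthogonal subspaces, no noise.
orthoFixture <- function(seed = 1, m = 60, perCluster = 15, dim = 3,
                         clusters = 3) {
  subspaceSim(m, rep(perCluster, clusters), rep(dim, clusters),
              noiseSd = 0, outlierFraction = 0, orthogonalize = TRUE,
              seed = seed)
}

# Conditions of the robust synthetic study: noisy union of subspaces with
# extreme-outlier columns, and a threshold sitting between the clean and
# outlier column norms (geometric midpoint).
robustFixture <- function(seed) {
  sim <- subspaceSim(60, rep(15L, 3), rep(3L, 3), noiseSd = 0.05,
                     outlierFraction = 0.1, outlierScale = 10,
                     seed = seed)
  cn <- columnNorms(sim$X)
  sim$theta <- sqrt(max(cn[!sim$outliers]) * min(cn[sim$outliers]))
  sim
}

relDiff <- function(a, b) abs(a - b) / max(abs(a), abs(b), 1e-300)
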
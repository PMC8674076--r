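## Fixture generator: data with exactly the structure the model assumes —
## samples from a union of low-dimensional linear subspaces, dense Gaussian
## noise, and a controlled fraction of extreme-outlier columns.

.withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Simulate a union-of-subspaces expression matrix
#'
#' For each cluster i an orthonormal basis \eqn{U_i} (m x r_i, mutually
#' orthogonal across clusters when \code{orthogonalize = TRUE}) is drawn and
#' its samples are formed as \eqn{U_i z} with standard-normal coefficients
#' z. I.i.d. Gaussian noise of standard deviation \code{noiseSd} is added,
#' and \code{round(outlierFraction * n)} randomly chosen columns are then
#' replaced by columns of uniformly random direction whose Euclidean norm is
#' \code{outlierScale} times the median column norm of the clean (noisy but
#' unreplaced) matrix. The output is deterministic given \code{seed}.
#'
#' The generator deliberately emulates only what the model assumes (linear
#' subspaces, dense noise, extreme-outlier columns); it does not emulate
#' expression-platform realism such as non-negativity, counts or heavy
#' tails.
#'
#' @param m Ambient dimension (number of genes).
#' @param samplesPerCluster Integer vector, samples in each cluster.
#' @param dims Integer vector, subspace dimension of each cluster
#'   (each <= m; their sum must be <= m when \code{orthogonalize}).
#' @param noiseSd Gaussian noise standard deviation (>= 0).
#' @param outlierFraction Fraction of columns replaced by outliers, in
#'   [0, 1).
#' @param outlierScale Outlier norm as a multiple of the median clean column
#'   norm (> 0).
#' @param orthogonalize If TRUE the cluster bases are mutually orthogonal.
#' @param seed Integer seed.
#' @return A list with \code{X} (m x n matrix with gene/sample dimnames),
#'   \code{labels} (integer ground truth, 1-based) and \code{outliers}
#'   (logical mask of replaced columns).
#' @examples
#' sim <- subspaceSim(20, c(5, 5), c(2, 2), seed = 1)
#' dim(sim$X)
#' @export
subspaceSim <- function(m, samplesPerCluster, dims, noiseSd = 0,
                        outlierFraction = 0, outlierScale = 10,
                        orthogonalize = TRUE, seed = 1) {
  c <- length(samplesPerCluster)
  if (length(dims) != c)
    stop("'dims' and 'samplesPerCluster' must have equal length",
         call. = FALSE)
  if (any(dims < 1L) || any(dims > m))
    stop("each subspace dimension must lie in 1..m", call. = FALSE)
  if (orthogonalize && sum(dims) > m)
    stop("sum of subspace dimensions exceeds the ambient dimension; ",
         "orthogonalization is infeasible", call. = FALSE)
  if (outlierFraction < 0 || outlierFraction >= 1)
    stop("'outlierFraction' must lie in [0, 1)", call. = FALSE)
  if (outlierScale <= 0) stop("'outlierScale' must be > 0", call. = FALSE)
  if (noiseSd < 0) stop("'noiseSd' must be >= 0", call. = FALSE)
  n <- sum(samplesPerCluster)
  .withSeed(seed, {
    if (orthogonalize) {
      Q <- qr.Q(qr(matrix(stats::rnorm(m * sum(dims)), m)))
      bases <- vector("list", c)
      off <- 0L
      for (i in seq_len(c)) {
        bases[[i]] <- Q[, off + seq_len(dims[i]), drop = FALSE]
        off <- off + dims[i]
      }
    } else {
      bases <- lapply(dims, function(r)
        qr.Q(qr(matrix(stats::rnorm(m * r), m))))
    }
    X <- matrix(0, m, n)
    labels <- integer(n)
    off <- 0L
    for (i in seq_len(c)) {
      ni <- samplesPerCluster[i]
      idx <- off + seq_len(ni)
      X[, idx] <- bases[[i]] %*%
        matrix(stats::rnorm(dims[i] * ni), dims[i])
      labels[idx] <- i
      off <- off + ni
    }
    if (noiseSd > 0)
      X <- X + matrix(stats::rnorm(m * n, sd = noiseSd), m)
    outliers <- rep(FALSE, n)
    nOut <- as.integer(round(outlierFraction * n))
    if (nOut > 0L) {
      med <- stats::median(sqrt(colSums(X^2)))
      idx <- sample.int(n, nOut)
      for (j in idx) {
        v <- stats::rnorm(m)
        X[, j] <- v / sqrt(sum(v^2)) * outlierScale * med
      }
      outliers[idx] <- TRUE
    }
    dimnames(X) <- list(paste0("gene", seq_len(m)),
                        paste0("sample", seq_len(n)))
    list(X = X, labels = labels, outliers = outliers)
  })
}

#' Canonical clean-recovery fixture
#'
#' The standard easy case: m = 60 genes, 3 clusters of 15 samples drawn from
#' mutually orthogonal 3-dimensional subspaces, no noise, no outliers. Any
#' subspace clustering method worth its salt must recover the ground-truth
#' partition exactly here.
#'
#' @param seed Integer seed.
#' @return As \code{\link{subspaceSim}} (the \code{outliers} mask is all
#'   FALSE).
#' @export
cleanRecoveryCase <- function(seed = 1) {
  subspaceSim(m = 60, samplesPerCluster = rep(15L, 3), dims = rep(3L, 3),
              noiseSd = 0, outlierFraction = 0, orthogonalize = TRUE,
              seed = seed)
}
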
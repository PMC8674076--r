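test_that("A-update satisfies its stationarity condition and closed forms", {
  set.seed(21)
  m <- 8; n <- 5
  X <- matrix(rnorm(m * n), m)
  E <- matrix(rnorm(m * n, sd = 0.1), m)
  Y <- matrix(rnorm(m * n, sd = 0.1), m)
  Aprev <- matrix(rnorm(m * n), m)
  for (mu in c(0.05, 1, 7)) {
    B <- X - E + Y / mu
    # k = 1: H = I exactly, so the update is the closed form mu/(2+mu) B
    A1 <- updateA(X, E, Y, mu, Aprev, k = 1)
    expect_equal(A1, (mu / (2 + mu)) * B, tolerance = 1e-14)
    # k < 1: residual of the linearized stationarity condition (H fixed)
    k <- 0.5
    A <- updateA(X, E, Y, mu, Aprev, k = k, ridge = 1e-10)
    S <- crossprod(Aprev)
    eg <- eigen((S + t(S)) / 2, symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    eps <- max(1e-10 * max(lam), 1e-12)
    H <- eg$vectors %*% (t(eg$vectors) * (k * (lam + eps)^(k - 1)))
    resid <- norm(2 * A %*% H + mu * (A - B), "F") / norm(B, "F")
    expect_lt(resid, 1e-8)
  }
  # penalty-dominates limit
  muBig <- 1e12
  A <- updateA(X, E, Y, muBig, Aprev, k = 0.7)
  B <- X - E + Y / muBig
  expect_lt(norm(A - B, "F") / norm(B, "F"), 1e-6)
  expect_error(updateA(X, E, Y, 0, Aprev, 1), "mu")
})

test_that("reweighting rule follows the capped-norm branches", {
  E <- cbind(c(0.5, 0), c(2, 0), c(0, 0))
  w <- unname(updateWeights(E, theta = 1))
  expect_equal(w[1], 1)                  # 1/(2 * 0.5)
  expect_equal(w[2], 0)                  # outlier branch
  expect_equal(w[3], 1 / (2 * 1e-10))    # floored zero column
  # boundary ||E_i|| = theta: strict inequality, weight 0
  Eb <- matrix(c(1, 0), 2, 1)
  expect_equal(unname(updateWeights(Eb, theta = 1)), 0)
  expect_equal(unname(updateWeights(Eb, theta = 1 + 1e-9)), 0.5,
               tolerance = 1e-6)
})

test_that("E-update is an exact per-column stationary point", {
  set.seed(22)
  m <- 7; n <- 6
  X <- matrix(rnorm(m * n), m)
  A <- matrix(rnorm(m * n), m)
  Y <- matrix(rnorm(m * n), m)
  mu <- 0.8; lambda <- 1.3
  o <- c(runif(n - 2), 0, 0.5)
  E <- updateE(X, A, Y, mu, lambda, o)
  Fm <- X - A + Y / mu
  # flagged outlier column (weight 0) keeps its full residual
  expect_equal(E[, n - 1], Fm[, n - 1], tolerance = 1e-14)
  # lambda = mu = 1, weight 0.5 halves the column
  E2 <- updateE(X, A, Y, 1, 1, rep(0.5, n))
  expect_equal(E2, (X - A + Y) / 2, tolerance = 1e-14)
  # Eq-17 stationarity holds to machine precision
  resid <- 2 * lambda * E %*% diag(o) + mu * (E - Fm)
  expect_lt(max(abs(resid)), 1e-12)
})

test_that("objective decomposes over cluster column blocks", {
  set.seed(23)
  m <- 10; n <- 8
  A <- matrix(rnorm(m * n), m)
  E <- matrix(rnorm(m * n, sd = 0.2), m)
  labels <- rep(1:2, each = 4)
  # k = 1, E = 0: the partition sum telescopes to the squared Frobenius norm
  p1 <- OrlrsParam(clusters = 2, k = 1, theta = Inf)
  expect_equal(objectiveValue(A, matrix(0, m, n), labels, p1),
               sum(A^2), tolerance = 1e-10)
  # A = 0, theta = Inf: lambda * L2,1
  p2 <- OrlrsParam(clusters = 2, lambda = 2.5, theta = Inf)
  expect_equal(objectiveValue(matrix(0, m, n), E, labels, p2),
               2.5 * l21Norm(E), tolerance = 1e-12)
  # k = 0.5, c = 2: term-by-term against the decomposition oracle
  p3 <- OrlrsParam(clusters = 2, lambda = 0.7, theta = 0.9, k = 0.5)
  manual <- oracleSchattenSum(A[, 1:4], 1) + oracleSchattenSum(A[, 5:8], 1) +
    0.7 * sum(pmin(sqrt(colSums(E^2)), 0.9))
  expect_equal(objectiveValue(A, E, labels, p3), manual, tolerance = 1e-10)
  expect_error(objectiveValue(A, E, rep(3L, n), p3), "labels")
})

test_that("zero-padded blocks and plain submatrices give equal objectives", {
  set.seed(24)
  A <- matrix(rnorm(30), 5, 6)
  labels <- c(1L, 2L, 1L, 2L, 2L, 1L)
  padded <- function(i) {
    Ai <- A
    Ai[, labels != i] <- 0
    Ai
  }
  for (k in c(0.5, 1)) {
    direct <- lowRankTerm(A[, labels == 1], k) +
      lowRankTerm(A[, labels == 2], k)
    pad <- lowRankTerm(padded(1), k) + lowRankTerm(padded(2), k)
    expect_equal(direct, pad, tolerance = 1e-10)
  }
})
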
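test_that("both solver modes recover a clean union of orthogonal subspaces", {
  sim <- cleanRecoveryCase(seed = 1)
  for (mode in c("orlrs", "lrs")) {
    p <- OrlrsParam(clusters = 3, theta = Inf, k = 1, seed = 4, mode = mode)
    fit <- orlrs(sim$X, p)
    expect_s4_class(fit, "OrlrsFit")
    expect_equal(clusteringAccuracy(sim$labels, clusterLabels(fit)), 1)
    expect_equal(nmi(sim$labels, clusterLabels(fit)), 1)
    # partition property: every sample carries exactly one valid label
    expect_true(all(clusterLabels(fit) %in% 1:3))
    expect_length(clusterLabels(fit), 45)
  }
})

test_that("the ALM loop reaches feasibility and records coherent traces", {
  sim <- robustFixture(seed = 2)
  p <- OrlrsParam(clusters = 3, theta = sim$theta, seed = 4)
  fit <- orlrs(sim$X, p, blockTrace = TRUE)
  expect_true(isConverged(fit))
  expect_lt(fit@finalResidual, 1e-6)
  expect_lte(fit@nOuter, 200)
  expect_equal(length(objectiveTrace(fit)), fit@nOuter)
  expect_equal(length(residualTrace(fit)), fit@nOuter)
  bt <- blockTrace(fit)
  expect_setequal(unique(bt$step), c("start", "A", "E", "I"))
  # the recorded final objective matches an independent recomputation
  expect_equal(utils::tail(objectiveTrace(fit), 1),
               objectiveValue(lowRankMatrix(fit), noiseMatrix(fit),
                              clusterLabels(fit), p),
               tolerance = 1e-10)
  # X = A + E holds at convergence
  expect_lt(norm(lowRankMatrix(fit) + noiseMatrix(fit) - sim$X, "F") /
              norm(sim$X, "F"), 1e-6)
})

test_that("an infinite threshold and a never-binding threshold are identical", {
  sim <- robustFixture(seed = 3)
  p1 <- OrlrsParam(clusters = 3, theta = Inf, seed = 2)
  bigTheta <- 10 * max(columnNorms(sim$X))
  p2 <- OrlrsParam(clusters = 3, theta = bigTheta, seed = 2)
  f1 <- orlrs(sim$X, p1)
  f2 <- orlrs(sim$X, p2)
  expect_identical(clusterLabels(f1), clusterLabels(f2))
  expect_equal(objectiveTrace(f1), objectiveTrace(f2), tolerance = 0)
  expect_equal(residualTrace(f1), residualTrace(f2), tolerance = 0)
  expect_equal(noiseWeights(f1), noiseWeights(f2), tolerance = 0)
  expect_false(any(noiseWeights(f2) == 0))
  # and the final objective decomposes with the plain L2,1 norm
  expect_equal(utils::tail(objectiveTrace(f1), 1),
               sum(vapply(1:3, function(i)
                 lowRankTerm(lowRankMatrix(f1)[, clusterLabels(f1) == i,
                                               drop = FALSE], 1),
                 numeric(1))) + l21Norm(noiseMatrix(f1)),
               tolerance = 1e-8)
})

test_that("column permutation of the input permutes the labels identically", {
  sim <- robustFixture(seed = 5)
  n <- ncol(sim$X)
  set.seed(99)
  perm <- sample(n)
  init <- kmeansInit(sim$X, 3, seed = 11)
  p <- OrlrsParam(clusters = 3, theta = sim$theta, seed = 11)
  f1 <- orlrs(sim$X, p, init = init)
  f2 <- orlrs(sim$X[, perm], p, init = init[perm])
  expect_identical(clusterLabels(f2), clusterLabels(f1)[perm])
})

test_that("singleton-cluster partitions price each column by its norm", {
  set.seed(41)
  X <- matrix(rnorm(30), 5, 6)
  p <- OrlrsParam(clusters = 6, theta = Inf, k = 0.5)
  # every sample its own cluster: each block is one column, whose single
  # singular value is the column norm, so the objective is sum ||X_j||^(2k)
  expect_equal(objectiveValue(X, matrix(0, 5, 6), 1:6, p),
               sum(columnNorms(X)^(2 * 0.5)), tolerance = 1e-10)
})

test_that("the robust mode flags outliers that the baseline cannot model", {
  sim <- robustFixture(seed = 7)
  p <- OrlrsParam(clusters = 3, theta = sim$theta, seed = 2)
  fit <- orlrs(sim$X, p)
  expect_identical(outlierFlags(fit), sim$outliers)
  expect_true(all(columnNorms(noiseMatrix(fit))[sim$outliers] >= sim$theta))
  flrs <- orlrs(sim$X, OrlrsParam(clusters = 3, mode = "lrs", seed = 2))
  expect_false(any(outlierFlags(flrs)))
})

test_that("restarts select a run and inputs are validated", {
  sim <- cleanRecoveryCase(seed = 1)
  p <- OrlrsParam(clusters = 3, mode = "lrs", restarts = 3, seed = 1)
  fit <- orlrs(sim$X, p)
  expect_s4_class(fit, "OrlrsFit")
  expect_error(orlrs(sim$X, OrlrsParam(clusters = 46)), "exceeds")
  expect_error(orlrs(sim$X[, 1, drop = FALSE], OrlrsParam(clusters = 2)),
               "samples")
  expect_error(orlrs(sim$X, OrlrsParam(clusters = 3), init = rep(5L, 45)),
               "labels")
  bad <- sim$X
  bad[1, 1] <- NA
  expect_error(orlrs(bad, OrlrsParam(clusters = 3)), "non-finite")
})

test_that("SummarizedExperiment input dispatches onto its first assay", {
  sim <- cleanRecoveryCase(seed = 1)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = sim$X))
  p <- OrlrsParam(clusters = 3, mode = "lrs", seed = 4)
  fse <- orlrs(se, p)
  fm <- orlrs(sim$X, p)
  expect_identical(clusterLabels(fse), clusterLabels(fm))
})

test_that("parameter validity catches nonsense configurations", {
  expect_error(OrlrsParam(clusters = 1), "clusters")
  expect_error(OrlrsParam(lambda = 0), "lambda")
  expect_error(OrlrsParam(k = 1.5), "k")
  expect_error(OrlrsParam(theta = -1), "theta")
  expect_error(OrlrsParam(mu0 = 10, muMax = 1), "muMax")
  expect_error(OrlrsParam(restarts = 0), "restarts")
  expect_output(show(OrlrsParam()), "OrlrsParam")
  sim <- cleanRecoveryCase(1)
  fit <- orlrs(sim$X, OrlrsParam(clusters = 3, mode = "lrs", seed = 4))
  expect_output(show(fit), "OrlrsFit")
})
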
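## Outer solver loops: the full robust model (ALM over A, E and the
## indicators) and the noiseless one-step baseline.

.validateExprMatrix <- function(X) {
  X <- as.matrix(X)
  if (!is.numeric(X)) stop("expression matrix must be numeric", call. = FALSE)
  if (nrow(X) < 1L || ncol(X) < 2L)
    stop("expression matrix needs >= 1 gene and >= 2 samples", call. = FALSE)
  .assertFinite(X, "expression matrix")
  if (is.null(rownames(X))) rownames(X) <- paste0("gene", seq_len(nrow(X)))
  if (is.null(colnames(X))) colnames(X) <- paste0("sample", seq_len(ncol(X)))
  X
}

.divergenceError <- function(iter) {
  stop(structure(
    class = c("orlrsDivergence", "error", "condition"),
    list(message = sprintf(
           "solver diverged: non-finite values at outer iteration %d", iter),
         call = NULL)))
}

.orlrsOnce <- function(X, param, init, trace.blocks = FALSE) {
  n <- ncol(X)
  c <- param@clusters
  labels <- .checkLabels(init, c, n)
  A <- X
  E <- matrix(0, nrow(X), n)
  Y <- matrix(0, nrow(X), n)
  mu <- param@mu0
  normX <- sqrt(sum(X^2))
  objTrace <- numeric(0)
  resTrace <- numeric(0)
  bIter <- integer(0); bStep <- character(0)
  bObj <- numeric(0); bMerit <- numeric(0)
  recBlock <- function(it, step, obj, merit) {
    bIter[[length(bIter) + 1L]] <<- it
    bStep[[length(bStep) + 1L]] <<- step
    bObj[[length(bObj) + 1L]] <<- obj
    bMerit[[length(bMerit) + 1L]] <<- merit
  }
  converged <- FALSE
  prevObj <- NA_real_
  nOuter <- 0L
  for (t in seq_len(param@maxOuter)) {
    nOuter <- t
    if (trace.blocks)
      recBlock(t, "start", objectiveValue(A, E, labels, param),
               .meritValue(X, A, E, labels, param, Y, mu))
    A <- updateA(X, E, Y, mu, A, param@k, param@ridge)
    if (!all(is.finite(A))) .divergenceError(t)
    if (trace.blocks)
      recBlock(t, "A", objectiveValue(A, E, labels, param),
               .meritValue(X, A, E, labels, param, Y, mu))
    o <- updateWeights(E, param@theta, param@epsNorm)
    E <- updateE(X, A, Y, mu, param@lambda, o)
    if (!all(is.finite(E))) .divergenceError(t)
    if (trace.blocks)
      recBlock(t, "E", objectiveValue(A, E, labels, param),
               .meritValue(X, A, E, labels, param, Y, mu))
    labels <- updateIndicators(A, labels, c, param@k, param@ridge,
                               param@maxInner)
    if (trace.blocks)
      recBlock(t, "I", objectiveValue(A, E, labels, param),
               .meritValue(X, A, E, labels, param, Y, mu))
    R <- A + E - X
    res <- sqrt(sum(R^2)) / normX
    obj <- objectiveValue(A, E, labels, param)
    objTrace[t] <- obj
    resTrace[t] <- res
    Y <- Y - mu * R
    mu <- min(param@rho * mu, param@muMax)
    if (!is.na(prevObj) && res < param@tolResidual &&
        abs(obj - prevObj) <= param@tolObjective * max(1, abs(prevObj))) {
      converged <- TRUE
      break
    }
    prevObj <- obj
  }
  weights <- unname(updateWeights(E, param@theta, param@epsNorm))
  new("OrlrsFit",
      labels = as.integer(labels), sampleIds = colnames(X),
      A = A, E = E, weights = weights,
      outlierFlags = unname(columnNorms(E) >= param@theta),
      objectiveTrace = objTrace, residualTrace = resTrace,
      blockTrace = data.frame(iteration = bIter, step = bStep,
                              objective = bObj, merit = bMerit,
                              stringsAsFactors = FALSE),
      converged = converged, nOuter = nOuter,
      finalResidual = utils::tail(resTrace, 1), param = param)
}

.lrsOnce <- function(X, param, init) {
  n <- ncol(X)
  c <- param@clusters
  labels <- .checkLabels(init, c, n)
  objTrace <- .partitionValue(X, labels, c, param@k)
  converged <- FALSE
  nOuter <- 0L
  for (t in seq_len(param@maxOuter)) {
    nOuter <- t
    nxt <- updateIndicators(X, labels, c, param@k, param@ridge, 1)
    objTrace[t + 1L] <- .partitionValue(X, nxt, c, param@k)
    if (identical(nxt, labels)) {
      converged <- TRUE
      labels <- nxt
      break
    }
    labels <- nxt
  }
  new("OrlrsFit",
      labels = as.integer(labels), sampleIds = colnames(X),
      A = X, E = matrix(0, nrow(X), n),
      weights = rep(NA_real_, n),
      outlierFlags = rep(FALSE, n),
      objectiveTrace = objTrace, residualTrace = numeric(0),
      blockTrace = data.frame(iteration = integer(0), step = character(0),
                              objective = numeric(0), merit = numeric(0),
                              stringsAsFactors = FALSE),
      converged = converged, nOuter = nOuter,
      finalResidual = 0, param = param)
}

.fitMatrix <- function(x, param, init = NULL, blockTrace = FALSE) {
  X <- .validateExprMatrix(x)
  validObject(param)
  if (param@clusters > ncol(X))
    stop("'clusters' exceeds the number of samples", call. = FALSE)
  runOne <- function(initLabels) {
    if (param@mode == "lrs") .lrsOnce(X, param, initLabels)
    else .orlrsOnce(X, param, initLabels, trace.blocks = blockTrace)
  }
  fits <- vector("list", param@restarts)
  for (r in seq_len(param@restarts)) {
    initLabels <- if (!is.null(init) && r == 1L) init
                  else kmeansInit(X, param@clusters,
                                  seed = param@seed + r - 1L)
    fits[[r]] <- runOne(initLabels)
  }
  finals <- vapply(fits, function(f) utils::tail(f@objectiveTrace, 1),
                   numeric(1))
  fits[[which.min(finals)]]
}

#' @describeIn orlrs Fit on a numeric genes-by-samples matrix.
#'
#' Initializes \eqn{A = X}, \eqn{E = 0}, \eqn{Y = 0}, \eqn{\mu = \mu_0} (a
#' feasible start) and, per outer iteration, performs the A-update, one
#' reweighting pass followed by the E-update (the weights lag one step), the
#' indicator refinement, then the multiplier step
#' \eqn{Y \leftarrow Y - \mu(A + E - X)} (the sign matching the
#' \eqn{+Y/\mu} convention inside B and F) and the penalty growth
#' \eqn{\mu \leftarrow \min(\rho\mu, \mu_{max})}. Stops when the relative
#' feasibility residual falls below \code{tolResidual} and the relative
#' objective change below \code{tolObjective}, or at \code{maxOuter}. With
#' \code{restarts > 1} the model is refit from distinct K-means seeds
#' (\code{seed}, \code{seed + 1}, ...) and the run with the lowest final
#' objective is returned. In \code{mode = "lrs"} the noiseless baseline runs
#' the indicator refinement directly on X (no E, no ALM).
#'
#' @param init Optional integer labels (1..clusters) to initialize the
#'   indicators; defaults to seeded K-means on the sample columns. When
#'   supplied it is used for the first restart only.
#' @param blockTrace If TRUE, record the objective and the
#'   augmented-Lagrangian merit after every block update (slower; for
#'   diagnostics and descent checks).
#' @export
setMethod("orlrs", "matrix", function(x, param = OrlrsParam(), init = NULL,
                                      blockTrace = FALSE) {
  .fitMatrix(x, param, init = init, blockTrace = blockTrace)
})

#' @describeIn orlrs Fit on the first assay of a
#'   \code{SummarizedExperiment}.
#' @export
setMethod("orlrs", "SummarizedExperiment",
          function(x, param = OrlrsParam(), init = NULL,
                   blockTrace = FALSE) {
  .fitMatrix(SummarizedExperiment::assay(x, 1), param, init = init,
             blockTrace = blockTrace)
})
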
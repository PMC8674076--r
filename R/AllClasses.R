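#' @import methods
NULL

#' Solver parameters for one-step robust low-rank subspace segmentation
#'
#' Container for every tunable of the solver: the model hyperparameters
#' (cluster count \code{clusters}, noise balance \code{lambda}, capped-norm
#' threshold \code{theta}, Schatten exponent \code{k}), the augmented
#' Lagrange multiplier schedule (\code{mu0}, \code{rho}, \code{muMax}), the
#' eigenvalue ridge used for fractional matrix powers (\code{ridge}, a factor
#' relative to the largest eigenvalue, floored at 1e-12 absolute), iteration
#' caps and tolerances, the restart protocol, the random seed, and the solver
#' mode (\code{"orlrs"} for the full robust model, \code{"lrs"} for the
#' noiseless one-step baseline).
#'
#' @slot clusters integer, number of clusters c (>= 2; <= n is checked at fit
#'   time).
#' @slot lambda positive balance between the low-rank term and the capped
#'   noise term.
#' @slot theta positive capped-norm threshold; \code{Inf} recovers the L2,1
#'   norm.
#' @slot k Schatten exponent in (0, 1].
#' @slot mu0,rho,muMax initial penalty, growth factor (>= 1) and cap of the
#'   ALM penalty parameter mu.
#' @slot ridge relative eigenvalue ridge for fractional powers.
#' @slot epsNorm floor on column norms inside the reweighting rule (the
#'   weight 1/(2||E_i||) is otherwise singular at ||E_i|| = 0).
#' @slot maxOuter,maxInner outer ALM iteration cap and indicator-refinement
#'   inner cap.
#' @slot tolResidual,tolObjective stopping tolerances on the relative
#'   feasibility residual ||A+E-X||_F/||X||_F and the relative objective
#'   change.
#' @slot restarts number of K-means-seeded restarts (the best-objective run
#'   is returned).
#' @slot seed integer seed controlling K-means initialization.
#' @slot mode \code{"orlrs"} or \code{"lrs"}.
#' @export
setClass("OrlrsParam",
  representation(
    clusters = "integer",
    lambda = "numeric",
    theta = "numeric",
    k = "numeric",
    mu0 = "numeric",
    rho = "numeric",
    muMax = "numeric",
    ridge = "numeric",
    epsNorm = "numeric",
    maxOuter = "integer",
    maxInner = "integer",
    tolResidual = "numeric",
    tolObjective = "numeric",
    restarts = "integer",
    seed = "integer",
    mode = "character"
  ),
  prototype(
    clusters = 2L, lambda = 1, theta = Inf, k = 1,
    mu0 = 1e-2, rho = 1.1, muMax = 1e8,
    ridge = 1e-10, epsNorm = 1e-10,
    maxOuter = 200L, maxInner = 30L,
    tolResidual = 1e-6, tolObjective = 1e-8,
    restarts = 1L, seed = 1L, mode = "orlrs"
  )
)

setValidity("OrlrsParam", function(object) {
  msg <- character(0)
  if (length(object@clusters) != 1L || object@clusters < 2L)
    msg <- c(msg, "'clusters' must be a single integer >= 2")
  if (object@lambda <= 0) msg <- c(msg, "'lambda' must be > 0")
  if (is.na(object@theta) || object@theta <= 0)
    msg <- c(msg, "'theta' must be > 0 (Inf allowed)")
  if (object@k <= 0 || object@k > 1) msg <- c(msg, "'k' must lie in (0, 1]")
  if (object@mu0 <= 0) msg <- c(msg, "'mu0' must be > 0")
  if (object@rho < 1) msg <- c(msg, "'rho' must be >= 1")
  if (object@mu0 > object@muMax) msg <- c(msg, "'mu0' must be <= 'muMax'")
  if (object@ridge <= 0) msg <- c(msg, "'ridge' must be > 0")
  if (object@epsNorm <= 0) msg <- c(msg, "'epsNorm' must be > 0")
  if (object@maxOuter < 1L) msg <- c(msg, "'maxOuter' must be >= 1")
  if (object@maxInner < 0L) msg <- c(msg, "'maxInner' must be >= 0")
  if (object@tolResidual <= 0 || object@tolObjective <= 0)
    msg <- c(msg, "tolerances must be > 0")
  if (object@restarts < 1L) msg <- c(msg, "'restarts' must be >= 1")
  if (!object@mode %in% c("orlrs", "lrs"))
    msg <- c(msg, "'mode' must be \"orlrs\" or \"lrs\"")
  if (length(msg)) msg else TRUE
})

#' Construct an OrlrsParam object
#'
#' @param clusters Number of clusters (>= 2).
#' @param lambda Balance parameter of the capped noise term (default 1, the
#'   middle of the useful 0.1--2 range on expression data).
#' @param theta Capped-norm threshold separating ordinary noise columns from
#'   extreme outliers. There is no universal default: it must be chosen per
#'   data set (or via the quantile rule of the CLI). \code{Inf} disables the
#'   cap, recovering plain L2,1 regularization.
#' @param k Schatten exponent in (0, 1] (default 1).
#' @param mu0,rho,muMax ALM penalty schedule (defaults 1e-2, 1.1, 1e8).
#' @param ridge Relative eigenvalue ridge for fractional matrix powers
#'   (default 1e-10; absolute floor 1e-12).
#' @param epsNorm Column-norm floor inside the reweighting rule (default
#'   1e-10).
#' @param maxOuter,maxInner Iteration caps (defaults 200 and 30).
#' @param tolResidual,tolObjective Stopping tolerances (defaults 1e-6, 1e-8).
#' @param restarts Number of K-means-seeded restarts (default 1).
#' @param seed Integer seed for K-means initialization.
#' @param mode \code{"orlrs"} (robust, default) or \code{"lrs"} (noiseless
#'   baseline).
#' @return An \linkS4class{OrlrsParam} object.
#' @examples
#' OrlrsParam(clusters = 3, theta = 5)
#' @export
OrlrsParam <- function(clusters = 2, lambda = 1, theta = Inf, k = 1,
                       mu0 = 1e-2, rho = 1.1, muMax = 1e8,
                       ridge = 1e-10, epsNorm = 1e-10,
                       maxOuter = 200, maxInner = 30,
                       tolResidual = 1e-6, tolObjective = 1e-8,
                       restarts = 1, seed = 1, mode = c("orlrs", "lrs")) {
  new("OrlrsParam",
      clusters = as.integer(clusters), lambda = as.numeric(lambda),
      theta = as.numeric(theta), k = as.numeric(k),
      mu0 = as.numeric(mu0), rho = as.numeric(rho), muMax = as.numeric(muMax),
      ridge = as.numeric(ridge), epsNorm = as.numeric(epsNorm),
      maxOuter = as.integer(maxOuter), maxInner = as.integer(maxInner),
      tolResidual = as.numeric(tolResidual),
      tolObjective = as.numeric(tolObjective),
      restarts = as.integer(restarts), seed = as.integer(seed),
      mode = match.arg(mode))
}

#' Result of a one-step robust low-rank subspace segmentation fit
#'
#' Holds the final cluster labels (integers 1..c), the learned low-rank
#' representation A and noise matrix E, the final reweighting diagonal, the
#' per-iteration objective and feasibility traces, an optional per-block
#' trace (objective and augmented-Lagrangian merit recorded after each A, E
#' and indicator update), outlier flags (columns whose final noise norm
#' reaches the threshold theta), and convergence diagnostics.
#'
#' @slot labels integer vector of cluster labels (1-based).
#' @slot sampleIds character vector of sample identifiers.
#' @slot A,E the low-rank representation and noise matrices.
#' @slot weights final reweighting diagonal (0 exactly on flagged outliers).
#' @slot outlierFlags logical; TRUE where the final ||E_i||_2 >= theta.
#' @slot objectiveTrace,residualTrace per-outer-iteration objective values
#'   and relative feasibility residuals.
#' @slot blockTrace data.frame with one row per block update (columns
#'   iteration, step, objective, merit), empty unless block tracing was
#'   requested.
#' @slot converged,nOuter,finalResidual stopping diagnostics.
#' @slot param the \linkS4class{OrlrsParam} used.
#' @export
setClass("OrlrsFit",
  representation(
    labels = "integer",
    sampleIds = "character",
    A = "matrix",
    E = "matrix",
    weights = "numeric",
    outlierFlags = "logical",
    objectiveTrace = "numeric",
    residualTrace = "numeric",
    blockTrace = "data.frame",
    converged = "logical",
    nOuter = "integer",
    finalResidual = "numeric",
    param = "OrlrsParam"
  )
)

setValidity("OrlrsFit", function(object) {
  msg <- character(0)
  n <- length(object@labels)
  if (anyNA(object@labels) || any(object@labels < 1L) ||
      any(object@labels > object@param@clusters))
    msg <- c(msg, "labels must lie in 1..clusters")
  if (length(unique(object@labels)) > object@param@clusters)
    msg <- c(msg, "labels take more than 'clusters' distinct values")
  if (length(object@outlierFlags) != n)
    msg <- c(msg, "outlierFlags length must match labels")
  if (length(msg)) msg else TRUE
})

setMethod("show", "OrlrsParam", function(object) {
  cat("OrlrsParam\n")
  cat(sprintf("  mode=%s clusters=%d lambda=%g theta=%g k=%g\n",
              object@mode, object@clusters, object@lambda, object@theta,
              object@k))
  cat(sprintf("  ALM: mu0=%g rho=%g muMax=%g maxOuter=%d maxInner=%d\n",
              object@mu0, object@rho, object@muMax, object@maxOuter,
              object@maxInner))
  cat(sprintf("  tol: residual=%g objective=%g; restarts=%d seed=%d\n",
              object@tolResidual, object@tolObjective, object@restarts,
              object@seed))
})

setMethod("show", "OrlrsFit", function(object) {
  tab <- table(object@labels)
  cat(sprintf("OrlrsFit (%s): %d samples in %d clusters\n",
              object@param@mode, length(object@labels), length(tab)))
  cat("  cluster sizes:", paste(as.integer(tab), collapse = ", "), "\n")
  cat(sprintf("  outliers flagged: %d\n", sum(object@outlierFlags)))
  cat(sprintf("  converged: %s after %d iterations (residual %.3g)\n",
              object@converged, object@nOuter, object@finalResidual))
  if (length(object@objectiveTrace))
    cat(sprintf("  final objective: %.6g\n",
                utils::tail(object@objectiveTrace, 1)))
})
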
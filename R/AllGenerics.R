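#' Fit the one-step robust low-rank subspace segmentation model
#'
#' Dispatches on the expression matrix container; see the method for
#' \code{matrix} for the full contract.
#'
#' @param x A numeric genes-by-samples matrix or a
#'   \code{SummarizedExperiment} (the first assay is used).
#' @param param An \linkS4class{OrlrsParam}.
#' @param ... Passed to methods (\code{init}, \code{blockTrace}).
#' @return An \linkS4class{OrlrsFit}.
#' @export
setGeneric("orlrs", function(x, param = OrlrsParam(), ...)
  standardGeneric("orlrs"))

#' @describeIn OrlrsFit cluster labels (integer, 1-based)
#' @param object,x An \code{OrlrsFit}.
#' @export
setGeneric("clusterLabels", function(object) standardGeneric("clusterLabels"))

#' @describeIn OrlrsFit per-iteration objective values
#' @export
setGeneric("objectiveTrace", function(object) standardGeneric("objectiveTrace"))

#' @describeIn OrlrsFit per-iteration relative feasibility residuals
#' @export
setGeneric("residualTrace", function(object) standardGeneric("residualTrace"))

#' @describeIn OrlrsFit per-block-update objective/merit trace
#' @export
setGeneric("blockTrace", function(object) standardGeneric("blockTrace"))

#' @describeIn OrlrsFit logical outlier flags per sample
#' @export
setGeneric("outlierFlags", function(object) standardGeneric("outlierFlags"))

#' @describeIn OrlrsFit final reweighting diagonal (0 on flagged outliers)
#' @export
setGeneric("noiseWeights", function(object) standardGeneric("noiseWeights"))

#' @describeIn OrlrsFit TRUE if the stopping tolerances were met
#' @export
setGeneric("isConverged", function(object) standardGeneric("isConverged"))

#' @describeIn OrlrsFit the learned low-rank representation A
#' @export
setGeneric("lowRankMatrix", function(object) standardGeneric("lowRankMatrix"))

#' @describeIn OrlrsFit the learned noise matrix E
#' @export
setGeneric("noiseMatrix", function(object) standardGeneric("noiseMatrix"))

#' @rdname clusterLabels
#' @aliases clusterLabels,OrlrsFit-method
setMethod("clusterLabels", "OrlrsFit", function(object) object@labels)

#' @rdname objectiveTrace
setMethod("objectiveTrace", "OrlrsFit", function(object) object@objectiveTrace)

#' @rdname residualTrace
setMethod("residualTrace", "OrlrsFit", function(object) object@residualTrace)

#' @rdname blockTrace
setMethod("blockTrace", "OrlrsFit", function(object) object@blockTrace)

#' @rdname outlierFlags
setMethod("outlierFlags", "OrlrsFit", function(object) object@outlierFlags)

#' @rdname noiseWeights
setMethod("noiseWeights", "OrlrsFit", function(object) object@weights)

#' @rdname isConverged
setMethod("isConverged", "OrlrsFit", function(object) object@converged)

#' @rdname lowRankMatrix
setMethod("lowRankMatrix", "OrlrsFit", function(object) object@A)

#' @rdname noiseMatrix
setMethod("noiseMatrix", "OrlrsFit", function(object) object@E)
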
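#' Tissue label of every sample
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @return a factor of length \code{ncol(x)}, named by sample id, with levels
#'   in canonical tissue-tag order.
#' @export
setGeneric("tissueLabels", function(x) standardGeneric("tissueLabels"))

#' Canonical tissue-tag order
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @return character vector of distinct tissue tags in canonical order.
#' @export
setGeneric("tissueTags", function(x) standardGeneric("tissueTags"))

#' Planted role of every gene in a synthetic dataset
#'
#' @param x a \linkS4class{TissueExpressionSet} built by
#'   \code{\link{generateDataset}}.
#' @return named character vector mapping gene id to one of
#'   \code{"quantitative"}, \code{"enriched"}, \code{"noise"}.
#' @export
setGeneric("geneRoles", function(x) standardGeneric("geneRoles"))

#' Home tissue of every planted enriched gene
#'
#' @param x a \linkS4class{TissueExpressionSet} built by
#'   \code{\link{generateDataset}}.
#' @return named character vector mapping each enriched gene id to its home
#'   tissue tag (empty when no enriched genes were planted).
#' @export
setGeneric("enrichedHome", function(x) standardGeneric("enrichedHome"))

#' Multiclass Matthews correlation coefficient of a result
#' @param x a \linkS4class{CVResult}.
#' @return a single numeric in [-1, 1].
#' @export
setGeneric("mcc", function(x) standardGeneric("mcc"))

#' Overall accuracy (total correct over total samples)
#' @param x a \linkS4class{CVResult}.
#' @return a single numeric in [0, 1].
#' @export
setGeneric("tacc", function(x) standardGeneric("tacc"))

#' Per-tissue accuracies ACC_j
#' @param x a \linkS4class{CVResult}.
#' @return named numeric vector, one accuracy per tissue tag.
#' @export
setGeneric("classAccuracy", function(x) standardGeneric("classAccuracy"))

#' Confusion matrix (true tissues in rows, predicted in columns)
#' @param x a \linkS4class{CVResult}.
#' @return square integer count matrix with tissue-tag dimnames.
#' @export
setGeneric("confusion", function(x) standardGeneric("confusion"))

#' Ranked gene identifiers
#' @param x a \linkS4class{RankedFeatures}.
#' @return character vector in rank order.
#' @export
setGeneric("ranking", function(x) standardGeneric("ranking"))

#' Selection-time scores of a ranked gene list
#' @param x a \linkS4class{RankedFeatures}.
#' @return numeric vector parallel to \code{ranking(x)}.
#' @export
setGeneric("featureScores", function(x) standardGeneric("featureScores"))

#' Discrete states of a discretized expression matrix
#' @param x a \linkS4class{DiscretizedExpression}.
#' @return integer genes-by-samples matrix with entries in \{-1, 0, 1\}.
#' @export
setGeneric("states", function(x) standardGeneric("states"))

#' Evaluated feature-set sizes of an IFS curve
#' @param x an \linkS4class{IFSCurve}.
#' @return increasing integer vector.
#' @export
setGeneric("curveSizes", function(x) standardGeneric("curveSizes"))

#' Per-point results of an IFS curve
#' @param x an \linkS4class{IFSCurve}.
#' @return list of \linkS4class{CVResult}, parallel to \code{curveSizes(x)}.
#' @export
setGeneric("curveResults", function(x) standardGeneric("curveResults"))
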
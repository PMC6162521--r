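#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays colData
#'   rowData rowData<- colData<-
#' @importFrom S4Vectors DataFrame metadata metadata<-
NULL

#' Tissue-labeled expression matrix
#'
#' A \linkS4class{SummarizedExperiment} holding one genes-by-samples assay of
#' non-negative expression values (RPKM or a comparable unit) named
#' \code{"expr"}, with the tissue of origin of every sample in
#' \code{colData(x)$tissue}. The tissue column is a factor; its level order is
#' the canonical tissue-tag order used by every downstream report, confusion
#' matrix and indicator matrix, so no function in the package ever re-sorts
#' tags implicitly.
#'
#' Synthetic datasets produced by \code{\link{generateDataset}} additionally
#' carry \code{rowData(x)$role} (one of \code{"quantitative"},
#' \code{"enriched"}, \code{"noise"}) and, for enriched genes,
#' \code{rowData(x)$home_tissue}.
#'
#' @seealso \code{\link{TissueExpressionSet}} (constructor),
#'   \code{\link{tissueLabels}}, \code{\link{tissueTags}}
#' @export
setClass("TissueExpressionSet", contains = "SummarizedExperiment")

setValidity("TissueExpressionSet", function(object) {
    msg <- character()
    if (!("expr" %in% names(assays(object))))
        msg <- c(msg, "assay 'expr' is required")
    else {
        m <- assay(object, "expr")
        if (any(m < 0, na.rm = TRUE))
            msg <- c(msg, "expression values must be non-negative")
        if (anyNA(m))
            msg <- c(msg, "expression values must not contain NA")
    }
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "gene identifiers must be present and unique")
    if (is.null(colnames(object)) || anyDuplicated(colnames(object)))
        msg <- c(msg, "sample identifiers must be present and unique")
    if (!("tissue" %in% colnames(colData(object))))
        msg <- c(msg, "colData must contain a 'tissue' column")
    else {
        tis <- colData(object)$tissue
        if (!is.factor(tis))
            msg <- c(msg, "'tissue' must be a factor")
        else if (anyNA(tis))
            msg <- c(msg, "'tissue' must have no missing values")
        else if (any(!nzchar(levels(tis))))
            msg <- c(msg, "tissue tags must be non-empty strings")
    }
    if (length(msg)) msg else TRUE
})

#' Parameters of the synthetic expression-data generator
#'
#' Describes a synthetic bulk-expression study: how many tissues, how many
#' samples each contributes, and three planted gene populations laid over a
#' log-normal background. See \code{\link{generateDataset}} for the generative
#' model and \code{\link{syntheticSpec}} for defaults and units.
#'
#' @slot nTissues number of tissue classes (>= 2).
#' @slot samplesPerTissue integer vector of per-tissue sample counts.
#' @slot nQuantGenes planted quantitatively tissue-specific genes.
#' @slot nEnrichedGenes planted single-tissue-enriched genes.
#' @slot nNoiseGenes uninformative background genes.
#' @slot baseLogMean,baseLogSd natural-log mean and SD of the background
#'   log-normal law.
#' @slot effectSd SD of the per-gene, per-tissue log-mean shifts of
#'   quantitative genes (0 = no tissue signal).
#' @slot enrichmentFold fold-elevation of enriched genes in their home tissue.
#' @slot dropFactor multiplicative suppression of enriched genes outside the
#'   home tissue.
#' @slot zeroFraction fraction of non-home enriched values set to exactly 0.
#' @slot floor minimum expression of quantitative genes (> 0 so they are
#'   non-zero everywhere).
#' @slot seed integer seed; the dataset is a pure function of the spec.
#' @export
setClass("SyntheticSpec",
    representation(
        nTissues = "integer",
        samplesPerTissue = "integer",
        nQuantGenes = "integer",
        nEnrichedGenes = "integer",
        nNoiseGenes = "integer",
        baseLogMean = "numeric",
        baseLogSd = "numeric",
        effectSd = "numeric",
        enrichmentFold = "numeric",
        dropFactor = "numeric",
        zeroFraction = "numeric",
        floor = "numeric",
        seed = "integer"
    )
)

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    chk <- function(cond, text) if (!cond) msg <<- c(msg, text)
    chk(length(object@nTissues) == 1L && object@nTissues >= 2L,
        "nTissues: must be a single count >= 2")
    chk(length(object@samplesPerTissue) == object@nTissues,
        "samplesPerTissue: length must equal nTissues")
    chk(all(object@samplesPerTissue >= 1L),
        "samplesPerTissue: every entry must be >= 1")
    chk(object@nQuantGenes >= 0L, "nQuantGenes: must be >= 0")
    chk(object@nEnrichedGenes >= 0L, "nEnrichedGenes: must be >= 0")
    chk(object@nNoiseGenes >= 0L, "nNoiseGenes: must be >= 0")
    chk(object@baseLogSd > 0, "baseLogSd: must be > 0")
    chk(object@effectSd >= 0, "effectSd: must be >= 0")
    chk(object@enrichmentFold >= 1, "enrichmentFold: must be >= 1")
    chk(object@dropFactor >= 0 && object@dropFactor <= 1,
        "dropFactor: must be in [0, 1]")
    chk(object@zeroFraction >= 0 && object@zeroFraction <= 1,
        "zeroFraction: must be in [0, 1]")
    chk(object@floor >= 0, "floor: must be >= 0")
    chk(!(object@nQuantGenes > 0L && object@floor <= 0),
        "floor: must be > 0 when nQuantGenes > 0 (quantitative genes are non-zero in every tissue)")
    chk(length(object@seed) == 1L && !is.na(object@seed),
        "seed: must be a single integer")
    if (length(msg)) msg else TRUE
})

#' Discretized expression matrix
#'
#' Three-state (-1/0/+1) discretization of an expression matrix used by the
#' mutual-information machinery: per gene, values below mean - alpha*SD map to
#' -1, above mean + alpha*SD to +1, and to 0 in between.
#'
#' @slot states integer genes-by-samples matrix with values in \{-1, 0, 1\}.
#' @slot thresholds two-column (low, high) numeric matrix, one row per gene.
#' @slot alpha the width multiplier used.
#' @export
setClass("DiscretizedExpression",
    representation(states = "matrix", thresholds = "matrix", alpha = "numeric")
)

setValidity("DiscretizedExpression", function(object) {
    msg <- character()
    if (!all(object@states %in% c(-1L, 0L, 1L)))
        msg <- c(msg, "states must be -1, 0 or 1")
    if (nrow(object@thresholds) != nrow(object@states) ||
        ncol(object@thresholds) != 2L)
        msg <- c(msg, "thresholds must be a (genes x 2) matrix")
    if (any(object@thresholds[, 1L] > object@thresholds[, 2L]))
        msg <- c(msg, "low threshold must not exceed high threshold")
    if (length(msg)) msg else TRUE
})

#' Ranked gene list
#'
#' Ordered gene list produced by a feature-ranking procedure, most importantly
#' the greedy mRMR ranking of \code{\link{rankFeaturesMRMR}}. The order is the
#' selection order; \code{scores} holds each gene's criterion value at the
#' moment it was selected (relevance for the first gene, the
#' relevance-redundancy score thereafter).
#'
#' @slot ranking character vector of gene identifiers in rank order.
#' @slot scores numeric selection-time score per ranked gene.
#' @slot criterion label of the ranking criterion (e.g. "MID", "MIQ",
#'   "relevance").
#' @export
setClass("RankedFeatures",
    representation(ranking = "character", scores = "numeric",
                   criterion = "character")
)

setValidity("RankedFeatures", function(object) {
    msg <- character()
    if (anyDuplicated(object@ranking))
        msg <- c(msg, "ranking must not contain duplicate gene ids")
    if (length(object@scores) != length(object@ranking))
        msg <- c(msg, "scores and ranking must have equal length")
    if (length(object@criterion) != 1L)
        msg <- c(msg, "criterion must be a single string")
    if (length(msg)) msg else TRUE
})

#' Cross-validated classification result
#'
#' Confusion matrix and the derived performance measures for one evaluated
#' model: per-tissue accuracy ACC_j = n_j / N_j (n_j correct among the N_j
#' samples of tissue j), overall accuracy TACC = sum(n_j) / sum(N_j), and the
#' multiclass Matthews correlation coefficient (Gorodkin's covariance-ratio
#' generalization). Rows of the confusion matrix are true tissues, columns
#' predicted tissues, both in canonical tag order.
#'
#' @slot confusion N-by-N integer count matrix (true x predicted).
#' @slot acc named per-tissue accuracy vector.
#' @slot tacc overall accuracy in [0, 1].
#' @slot mcc multiclass MCC in [-1, 1].
#' @slot foldId opaque identifier of the fold partition that produced the
#'   pooled predictions ("" when not from cross-validation).
#' @export
setClass("CVResult",
    representation(confusion = "matrix", acc = "numeric", tacc = "numeric",
                   mcc = "numeric", foldId = "character")
)

setValidity("CVResult", function(object) {
    msg <- character()
    cm <- object@confusion
    if (nrow(cm) != ncol(cm))
        msg <- c(msg, "confusion matrix must be square")
    if (is.null(rownames(cm)) || !identical(rownames(cm), colnames(cm)))
        msg <- c(msg, "confusion matrix must carry identical row/col tissue tags")
    if (length(object@acc) != nrow(cm))
        msg <- c(msg, "acc must have one entry per tissue")
    if (length(object@tacc) != 1L || object@tacc < 0 || object@tacc > 1)
        msg <- c(msg, "tacc must be a single value in [0, 1]")
    if (length(object@mcc) != 1L || object@mcc < -1 - 1e-9 ||
        object@mcc > 1 + 1e-9)
        msg <- c(msg, "mcc must be a single value in [-1, 1]")
    if (length(msg)) msg else TRUE
})

#' SVM training parameters
#'
#' Contract for the classification stage: a polynomial-kernel support vector
#' machine trained by an SMO-type solver with one-vs-one multiclass voting,
#' preceded by per-feature min-max normalization to [0, 1] fitted on training
#' data only. Defaults mirror the standard SMO tool configuration: degree-1
#' polynomial kernel, C = 1, tolerance 0.001, normalized inputs.
#'
#' @slot degree polynomial kernel degree (>= 1).
#' @slot cost soft-margin cost C (> 0).
#' @slot tolerance solver stopping tolerance (> 0).
#' @slot logTransform apply log2(x + 1) to expression values before
#'   normalization (off by default; raw expression is modeled).
#' @export
setClass("SVMParams",
    representation(degree = "integer", cost = "numeric", tolerance = "numeric",
                   logTransform = "logical")
)

setValidity("SVMParams", function(object) {
    msg <- character()
    if (object@degree < 1L) msg <- c(msg, "degree must be >= 1")
    if (object@cost <= 0) msg <- c(msg, "cost must be > 0")
    if (object@tolerance <= 0) msg <- c(msg, "tolerance must be > 0")
    if (length(msg)) msg else TRUE
})

#' Incremental-feature-selection curve
#'
#' One cross-validated \linkS4class{CVResult} per evaluated feature-set size
#' i, where the feature set is the top-i prefix of a ranked gene list. All
#' points share a single fold partition so differences along the curve
#' reflect features, not fold noise.
#'
#' @slot sizes strictly increasing integer vector of evaluated prefix sizes.
#' @slot results list of \linkS4class{CVResult}, parallel to \code{sizes}.
#' @slot foldId the shared fold-partition identifier.
#' @export
setClass("IFSCurve",
    representation(sizes = "integer", results = "list", foldId = "character")
)

setValidity("IFSCurve", function(object) {
    msg <- character()
    if (length(object@sizes) != length(object@results))
        msg <- c(msg, "sizes and results must have equal length")
    if (is.unsorted(object@sizes, strictly = TRUE))
        msg <- c(msg, "sizes must be strictly increasing")
    if (!all(vapply(object@results, is, logical(1L), class2 = "CVResult")))
        msg <- c(msg, "results must all be CVResult objects")
    fid <- unique(vapply(object@results, function(r) r@foldId, character(1L)))
    if (length(fid) > 1L)
        msg <- c(msg, "all points must share one fold partition")
    if (length(msg)) msg else TRUE
})
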
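#' Construct a TissueExpressionSet
#'
#' Bundles a genes-by-samples expression matrix with the tissue of origin of
#' every sample into the container used by all downstream stages.
#'
#' @param expr numeric genes-by-samples matrix with unique row (gene) and
#'   column (sample) names; values must be non-negative.
#' @param tissue tissue tag per sample: either a factor/character vector of
#'   length \code{ncol(expr)} (optionally named by sample id) or a named
#'   vector covering every sample id.
#' @param tags optional canonical tag order; defaults to the factor levels of
#'   \code{tissue} or first appearance order.
#' @param rowData optional \code{DataFrame} of per-gene metadata.
#' @return a \linkS4class{TissueExpressionSet}.
#' @examples
#' m <- matrix(rpois(12, 5), 3, 4,
#'             dimnames = list(paste0("g", 1:3), paste0("s", 1:4)))
#' tes <- TissueExpressionSet(m, c("liver", "liver", "lung", "lung"))
#' tissueTags(tes)
#' @export
TissueExpressionSet <- function(expr, tissue, tags = NULL, rowData = NULL) {
    expr <- as.matrix(expr)
    attr(expr, "description") <- NULL
    if (is.null(rownames(expr)) || is.null(colnames(expr)))
        stop("expr must have gene row names and sample column names")
    if (!is.null(names(tissue)) && !is.factor(tissue)) {
        missing <- setdiff(colnames(expr), names(tissue))
        if (length(missing))
            stop("no tissue label for sample(s): ",
                 paste(utils::head(missing, 5L), collapse = ", "))
        tissue <- tissue[colnames(expr)]
    }
    if (length(tissue) != ncol(expr))
        stop("tissue must provide one label per sample")
    if (is.null(tags))
        tags <- if (is.factor(tissue)) levels(tissue) else unique(as.character(tissue))
    tissue <- factor(as.character(tissue), levels = tags)
    if (anyNA(tissue))
        stop("tissue contains labels outside the supplied tag order")
    cd <- DataFrame(tissue = tissue, row.names = colnames(expr))
    se <- SummarizedExperiment(assays = list(expr = expr), colData = cd)
    if (!is.null(rowData))
        rowData(se) <- rowData
    new("TissueExpressionSet", se)
}

#' @rdname tissueLabels
#' @export
setMethod("tissueLabels", "TissueExpressionSet", function(x) {
    out <- colData(x)$tissue
    names(out) <- colnames(x)
    out
})

#' @rdname tissueTags
#' @export
setMethod("tissueTags", "TissueExpressionSet", function(x)
    levels(colData(x)$tissue))

#' @rdname geneRoles
#' @export
setMethod("geneRoles", "TissueExpressionSet", function(x) {
    rd <- rowData(x)
    if (!("role" %in% colnames(rd)))
        stop("no planted gene roles: not a generated dataset")
    out <- as.character(rd$role)
    names(out) <- rownames(x)
    out
})

#' @rdname enrichedHome
#' @export
setMethod("enrichedHome", "TissueExpressionSet", function(x) {
    rd <- rowData(x)
    if (!all(c("role", "home_tissue") %in% colnames(rd)))
        stop("no planted gene roles: not a generated dataset")
    sel <- rd$role == "enriched"
    out <- as.character(rd$home_tissue[sel])
    names(out) <- rownames(x)[sel]
    out
})

#' Expression matrix of a TissueExpressionSet
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @return the genes-by-samples numeric matrix of the \code{"expr"} assay.
#' @export
exprMatrix <- function(x) assay(x, "expr")

setMethod("show", "TissueExpressionSet", function(object) {
    tab <- table(colData(object)$tissue)
    cat("TissueExpressionSet:", nrow(object), "genes x", ncol(object),
        "samples,", length(tab), "tissues\n")
    cat("  samples/tissue:", paste0(names(tab), "=", as.integer(tab),
        collapse = " "), "\n")
    if ("role" %in% colnames(rowData(object))) {
        rt <- table(rowData(object)$role)
        cat("  planted roles:", paste0(names(rt), "=", as.integer(rt),
            collapse = " "), "\n")
    }
    invisible(NULL)
})

#' @rdname mcc
#' @export
setMethod("mcc", "CVResult", function(x) x@mcc)

#' @rdname tacc
#' @export
setMethod("tacc", "CVResult", function(x) x@tacc)

#' @rdname classAccuracy
#' @export
setMethod("classAccuracy", "CVResult", function(x) x@acc)

#' @rdname confusion
#' @export
setMethod("confusion", "CVResult", function(x) x@confusion)

setMethod("show", "CVResult", function(object) {
    cat("CVResult over", nrow(object@confusion), "tissues,",
        sum(object@confusion), "samples\n")
    cat(sprintf("  TACC = %.4f   MCC = %.4f\n", object@tacc, object@mcc))
    cat(sprintf("  ACC_j range: %.4f .. %.4f\n",
                min(object@acc), max(object@acc)))
    invisible(NULL)
})

#' @rdname ranking
#' @export
setMethod("ranking", "RankedFeatures", function(x) x@ranking)

#' @rdname featureScores
#' @export
setMethod("featureScores", "RankedFeatures", function(x) {
    out <- x@scores
    names(out) <- x@ranking
    out
})

setMethod("show", "RankedFeatures", function(object) {
    n <- length(object@ranking)
    cat("RankedFeatures:", n, "genes, criterion", object@criterion, "\n")
    cat("  top:", paste(utils::head(object@ranking, 5L), collapse = ", "),
        if (n > 5L) "..." else "", "\n")
    invisible(NULL)
})

#' @rdname states
#' @export
setMethod("states", "DiscretizedExpression", function(x) x@states)

setMethod("show", "DiscretizedExpression", function(object) {
    cat("DiscretizedExpression:", nrow(object@states), "genes x",
        ncol(object@states), "samples (alpha =", object@alpha, ")\n")
    invisible(NULL)
})

#' @rdname curveSizes
#' @export
setMethod("curveSizes", "IFSCurve", function(x) x@sizes)

#' @rdname curveResults
#' @export
setMethod("curveResults", "IFSCurve", function(x) x@results)

setMethod("show", "IFSCurve", function(object) {
    mccs <- vapply(object@results, mcc, numeric(1L))
    cat("IFSCurve:", length(object@sizes), "points, i =",
        min(object@sizes), "..", max(object@sizes), "\n")
    cat(sprintf("  best MCC %.4f at i = %d\n", max(mccs),
                object@sizes[which.max(mccs)]))
    invisible(NULL)
})

setMethod("show", "SyntheticSpec", function(object) {
    cat("SyntheticSpec:", object@nTissues, "tissues,",
        sum(object@samplesPerTissue), "samples;",
        object@nQuantGenes, "quantitative +", object@nEnrichedGenes,
        "enriched +", object@nNoiseGenes, "noise genes\n")
    cat(sprintf("  background lognormal(%.2f, %.2f); effectSd %.2f; fold %.1f; floor %g; seed %d\n",
        object@baseLogMean, object@baseLogSd, object@effectSd,
        object@enrichmentFold, object@floor, object@seed))
    invisible(NULL)
})

setMethod("show", "SVMParams", function(object) {
    cat(sprintf("SVMParams: polynomial degree %d, C = %g, tolerance = %g, log2-transform %s\n",
        object@degree, object@cost, object@tolerance,
        if (object@logTransform) "on" else "off"))
    invisible(NULL)
})
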
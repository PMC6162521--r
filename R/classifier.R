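#' @importFrom e1071 svm
NULL

#' Construct SVM training parameters
#'
#' Defaults mirror the stock configuration of an SMO-trained SVM as shipped
#' by the common toolkits: degree-1 polynomial kernel, soft-margin cost
#' C = 1, solver tolerance 0.001, one-vs-one multiclass voting, and
#' per-feature min-max normalization of the inputs to [0, 1] (always fitted
#' on training data only; see \code{\link{trainSVM}}).
#'
#' @param degree polynomial kernel degree (default 1, i.e. a linear
#'   decision surface).
#' @param cost soft-margin cost C (default 1).
#' @param tolerance solver stopping tolerance (default 0.001).
#' @param logTransform apply log2(x + 1) to expression values before
#'   normalization. Off by default: the pipeline models raw expression
#'   values; the flag exists for sensitivity analysis.
#' @return an \linkS4class{SVMParams}.
#' @export
svmParams <- function(degree = 1L, cost = 1.0, tolerance = 0.001,
                      logTransform = FALSE) {
    new("SVMParams", degree = as.integer(degree), cost = as.numeric(cost),
        tolerance = as.numeric(tolerance),
        logTransform = as.logical(logTransform))
}

# Per-feature min-max statistics on training samples (rows = samples).
.fitMinMax <- function(m) {
    mins <- apply(m, 2L, min)
    rng <- apply(m, 2L, max) - mins
    list(mins = mins, ranges = rng)
}

# Apply fitted min-max scaling; a constant training feature maps to 0.
.applyMinMax <- function(m, norm) {
    out <- sweep(m, 2L, norm$mins)
    rng <- ifelse(norm$ranges == 0, 1, norm$ranges)
    out <- sweep(out, 2L, rng, "/")
    out[, norm$ranges == 0] <- 0
    out
}

.featureMatrix <- function(x, features, params) {
    m <- exprMatrix(x)
    unknown <- setdiff(features, rownames(m))
    if (length(unknown))
        stop("unknown gene id(s): ",
             paste(utils::head(unknown, 5L), collapse = ", "))
    fm <- t(m[features, , drop = FALSE])
    if (params@logTransform) fm <- log2(fm + 1)
    fm
}

#' Train a multi-class tissue SVM
#'
#' Fits a polynomial-kernel support vector machine on a gene subset: features
#' are min-max normalized to [0, 1] using statistics of the supplied
#' (training) samples only, and the multiclass problem is decomposed
#' one-vs-one with majority voting. The quadratic-programming solver is the
#' established SMO-type implementation of \pkg{e1071}/libsvm, driven by the
#' \linkS4class{SVMParams} contract; training is deterministic for fixed
#' inputs.
#'
#' @param x a \linkS4class{TissueExpressionSet} of training samples with at
#'   least 2 represented tissues.
#' @param features non-empty character vector of gene ids to use (typically a
#'   prefix of a \linkS4class{RankedFeatures} ranking).
#' @param params an \linkS4class{SVMParams}.
#' @return an object of class \code{"tissueSVM"}; use \code{predict} with a
#'   new \linkS4class{TissueExpressionSet} to obtain a factor of predicted
#'   tags.
#' @examples
#' tes <- generateDataset(syntheticSpec(nTissues = 2,
#'     samplesPerTissue = c(10, 10), nQuantGenes = 3, nEnrichedGenes = 0,
#'     nNoiseGenes = 5, effectSd = 2, seed = 1))
#' fit <- trainSVM(tes, rownames(tes)[1:3], svmParams())
#' mean(predict(fit, tes) == tissueLabels(tes))
#' @export
trainSVM <- function(x, features, params = svmParams()) {
    stopifnot(is(x, "TissueExpressionSet"))
    validObject(params)
    if (length(features) < 1L) stop("feature set must be non-empty")
    labs <- droplevels(tissueLabels(x))
    if (nlevels(labs) < 2L)
        stop("training data must contain at least 2 tissues")
    fm <- .featureMatrix(x, features, params)
    norm <- .fitMinMax(fm)
    fmN <- .applyMinMax(fm, norm)
    fit <- e1071::svm(x = fmN, y = labs, type = "C-classification",
                      kernel = "polynomial", degree = params@degree,
                      gamma = 1, coef0 = 0, cost = params@cost,
                      tolerance = params@tolerance, scale = FALSE)
    structure(list(fit = fit, features = features, norm = norm,
                   params = params, tags = tissueTags(x)),
              class = "tissueSVM")
}

#' @export
print.tissueSVM <- function(x, ...) {
    cat("tissueSVM:", length(x$features), "features,",
        length(x$fit$levels), "tissues,", x$fit$tot.nSV, "support vectors\n")
    invisible(x)
}

#' Predict tissues for new samples
#'
#' @param object a \code{"tissueSVM"} from \code{\link{trainSVM}}.
#' @param newdata a \linkS4class{TissueExpressionSet} containing all model
#'   genes.
#' @param ... unused.
#' @return factor of predicted tissue tags, named by sample id, with the
#'   model's canonical tag levels.
#' @export
predict.tissueSVM <- function(object, newdata, ...) {
    fm <- .featureMatrix(newdata, object$features, object$params)
    fmN <- .applyMinMax(fm, object$norm)
    p <- predict(object$fit, fmN)
    out <- factor(as.character(p), levels = object$tags)
    names(out) <- colnames(newdata)
    out
}

#' Stratified k-fold partition
#'
#' Assigns every sample to one of k folds, dealing the shuffled samples of
#' each tissue round-robin so per-tissue fold sizes differ by at most one.
#' Tissues with fewer than k samples simply leave some folds without a
#' representative of that tissue. The partition is a pure function of
#' (labels, k, seed) and carries a \code{"foldId"} attribute so downstream
#' results can assert that they share one partition.
#'
#' @param labels factor of tissue tags, one per sample.
#' @param k number of folds (>= 2; default 10).
#' @param seed integer seed.
#' @return integer vector of fold indices in 1..k, with attribute
#'   \code{"foldId"}.
#' @export
makeStratifiedFolds <- function(labels, k = 10L, seed = 1L) {
    k <- as.integer(k)
    if (k < 2L) stop("k must be >= 2")
    labels <- factor(labels)
    set.seed(seed)
    fold <- integer(length(labels))
    offset <- 0L
    for (tg in levels(labels)) {
        idx <- which(labels == tg)
        idx <- idx[sample.int(length(idx))]
        fold[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
        offset <- offset + length(idx)
    }
    attr(fold, "foldId") <- sprintf("k%d-seed%d-n%d", k, seed, length(labels))
    fold
}

#' Cross-validate an SVM on a feature set
#'
#' Stratified k-fold cross-validation (default 10-fold): for each fold, a
#' model is trained on the other k - 1 folds — with min-max normalization
#' refitted inside that training fold, so no statistic of held-out samples
#' leaks into training — and the held-out samples are predicted. The pooled
#' out-of-fold predictions (each sample predicted exactly once) are tallied
#' into a single \linkS4class{CVResult}.
#'
#' Pass a precomputed \code{folds} vector (from
#' \code{\link{makeStratifiedFolds}}) to share one partition across many
#' feature sets, as the IFS scan does.
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @param features non-empty character vector of gene ids.
#' @param k number of folds (ignored when \code{folds} is given).
#' @param seed fold-partition seed (ignored when \code{folds} is given).
#' @param params an \linkS4class{SVMParams}.
#' @param folds optional precomputed fold assignment.
#' @return a \linkS4class{CVResult}.
#' @export
crossValidate <- function(x, features, k = 10L, seed = 1L,
                          params = svmParams(), folds = NULL) {
    stopifnot(is(x, "TissueExpressionSet"))
    if (length(features) < 1L) stop("feature set must be non-empty")
    labs <- tissueLabels(x)
    if (is.null(folds)) folds <- makeStratifiedFolds(labs, k, seed)
    if (length(folds) != ncol(x))
        stop("folds must assign every sample")
    pred <- factor(rep(NA_character_, ncol(x)), levels = tissueTags(x))
    for (f in sort(unique(folds))) {
        testIdx <- which(folds == f)
        fit <- trainSVM(x[, -testIdx], features, params)
        pred[testIdx] <- predict(fit, x[, testIdx])
    }
    confusionFromLabels(labs, pred, tags = tissueTags(x),
                        foldId = attr(folds, "foldId") %||% "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
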
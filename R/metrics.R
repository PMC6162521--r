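#' Class-indicator matrix
#'
#' Encodes a label vector as the n-by-N 0/1 matrix with one column per class
#' tag in the given order; row i has a single 1 in the column of sample i's
#' class.
#'
#' @param labels factor or character vector of class labels.
#' @param tags class-tag order (columns); defaults to the factor levels.
#' @return integer n-by-N matrix with unit row sums.
#' @export
indicatorMatrix <- function(labels, tags = NULL) {
    if (is.null(tags))
        tags <- if (is.factor(labels)) levels(labels) else unique(as.character(labels))
    f <- factor(as.character(labels), levels = tags)
    if (anyNA(f)) stop("labels outside the supplied tag order")
    m <- matrix(0L, nrow = length(f), ncol = length(tags),
                dimnames = list(names(labels), tags))
    m[cbind(seq_along(f), as.integer(f))] <- 1L
    m
}

.asIndicatorPair <- function(truth, pred, tags) {
    if (is.matrix(truth) || is.matrix(pred)) {
        if (!is.matrix(truth) || !is.matrix(pred))
            stop("supply both truth and prediction as matrices, or neither")
        if (!identical(dim(truth), dim(pred)))
            stop("indicator matrices must share dimensions")
        chk <- function(m, what) {
            if (!all(m %in% c(0L, 1L)))
                stop(what, " indicator matrix must be 0/1")
            if (!all(rowSums(m) == 1L))
                stop(what, " indicator rows must each sum to exactly 1")
        }
        chk(truth, "truth"); chk(pred, "prediction")
        return(list(Y = truth, X = pred))
    }
    if (length(truth) != length(pred))
        stop("truth and prediction must have equal length")
    if (is.null(tags))
        tags <- if (is.factor(truth)) levels(truth) else
            unique(c(as.character(truth), as.character(pred)))
    list(Y = indicatorMatrix(truth, tags), X = indicatorMatrix(pred, tags))
}

#' Multiclass Matthews correlation coefficient
#'
#' Gorodkin's generalization of the Matthews correlation coefficient to N
#' classes: the normalized covariance between the truth and prediction
#' indicator matrices,
#' \deqn{MCC = cov(X, Y) / \sqrt{cov(X, X) \, cov(Y, Y)}}
#' with \eqn{cov(X, Y) = (1/N) \sum_k \sum_i (x_{ik} - \bar x_k)(y_{ik} -
#' \bar y_k)} over the class columns. The value lies in [-1, 1]: 1 is a
#' perfect classification, 0 no better than random guessing, and -1 total
#' misclassification (attained in the two-class case). For N = 2 it reduces
#' exactly to the classical binary Matthews coefficient. When the denominator
#' is 0 (a constant prediction or a single represented class carries no
#' discriminating information) the value is defined as 0.
#'
#' @param truth true class labels (factor/character) or an n-by-N 0/1
#'   indicator matrix.
#' @param pred predicted class labels or indicator matrix, same form as
#'   \code{truth}.
#' @param tags class-tag order used to build indicator matrices from label
#'   vectors; ignored when matrices are supplied.
#' @return a single numeric in [-1, 1].
#' @examples
#' truth <- rep(c("a", "b"), each = 5)
#' multiclassMCC(truth, truth)                    # 1
#' multiclassMCC(truth, rev(truth))               # -1
#' @export
multiclassMCC <- function(truth, pred, tags = NULL) {
    p <- .asIndicatorPair(truth, pred, tags)
    N <- ncol(p$Y)
    if (N < 2L) stop("at least 2 classes are required")
    Xc <- sweep(p$X, 2L, colMeans(p$X))
    Yc <- sweep(p$Y, 2L, colMeans(p$Y))
    covXY <- sum(Xc * Yc) / N
    covXX <- sum(Xc * Xc) / N
    covYY <- sum(Yc * Yc) / N
    den <- sqrt(covXX * covYY)
    if (den == 0) return(0)
    max(-1, min(1, covXY / den))
}

#' Per-class accuracies
#'
#' ACC_j = n_j / N_j, where n_j is the number of correctly predicted samples
#' of class j and N_j the number of samples of class j.
#'
#' @inheritParams multiclassMCC
#' @return named numeric vector of per-class accuracies in tag order.
#' @export
perClassAccuracy <- function(truth, pred, tags = NULL) {
    p <- .asIndicatorPair(truth, pred, tags)
    Nj <- colSums(p$Y)
    if (any(Nj == 0L))
        stop("class with no samples: ",
             paste(colnames(p$Y)[Nj == 0L], collapse = ", "))
    nj <- colSums(p$Y * p$X)
    out <- nj / Nj
    names(out) <- colnames(p$Y)
    out
}

#' Overall accuracy
#'
#' TACC = sum(n_j) / sum(N_j): total correctly predicted samples over total
#' samples, identically the N_j-weighted mean of the per-class accuracies.
#'
#' @inheritParams multiclassMCC
#' @return a single numeric in [0, 1].
#' @export
overallAccuracy <- function(truth, pred, tags = NULL) {
    p <- .asIndicatorPair(truth, pred, tags)
    sum(p$Y * p$X) / nrow(p$Y)
}

#' Build a CVResult from pooled true and predicted labels
#'
#' Tallies the confusion matrix in the given tag order and fills every
#' derived measure (per-class accuracy, overall accuracy, multiclass MCC).
#'
#' @param truth true class labels.
#' @param pred predicted class labels, parallel to \code{truth}.
#' @param tags class-tag order; defaults to the levels of \code{truth}.
#' @param foldId optional identifier of the fold partition that produced the
#'   predictions.
#' @return a \linkS4class{CVResult}.
#' @export
confusionFromLabels <- function(truth, pred, tags = NULL, foldId = "") {
    if (is.null(tags))
        tags <- if (is.factor(truth)) levels(truth) else
            unique(c(as.character(truth), as.character(pred)))
    tf <- factor(as.character(truth), levels = tags)
    pf <- factor(as.character(pred), levels = tags)
    if (anyNA(tf) || anyNA(pf)) stop("labels outside the supplied tag order")
    cm <- table(true = tf, predicted = pf)
    cm <- matrix(as.integer(cm), nrow = length(tags),
                 dimnames = list(tags, tags))
    new("CVResult",
        confusion = cm,
        acc = perClassAccuracy(tf, pf, tags),
        tacc = overallAccuracy(tf, pf, tags),
        mcc = multiclassMCC(tf, pf, tags),
        foldId = as.character(foldId))
}

#' Write a per-tissue performance report
#'
#' Tab-separated report in the layout of a per-tissue accuracy figure: one
#' ACC row per tissue (tag, correct n_j, total N_j, ACC_j) followed by TACC
#' and MCC footer rows.
#'
#' @param x a \linkS4class{CVResult}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writeCVReport <- function(x, path) {
    stopifnot(is(x, "CVResult"))
    cm <- x@confusion
    df <- data.frame(tissue = rownames(cm),
                     n_correct = diag(cm),
                     n_total = rowSums(cm),
                     ACC = x@acc)
    con <- file(path, "w")
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    writeLines(c(sprintf("TACC\t%.*g", 15L, x@tacc),
                 sprintf("MCC\t%.*g", 15L, x@mcc)), con)
    invisible(path)
}
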
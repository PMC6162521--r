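#' Incremental feature selection scan
#'
#' Evaluates growing prefixes of a ranked gene list: for each size i in the
#' scan range, the top-i genes form the feature set and are scored by
#' stratified k-fold cross-validation. One fold partition is drawn once
#' (from \code{seed}) and shared by every point, so differences along the
#' curve reflect the features, not fold noise. The conventional scan range
#' of 4..500 features keeps the quadratic-time tail of the scan affordable
#' on full-size expression panels; \code{step} > 1 thins the scan further.
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @param ranked a \linkS4class{RankedFeatures} (or character vector of gene
#'   ids in rank order).
#' @param iMin,iMax,step scan range over prefix sizes (defaults 4, 500, 1);
#'   \code{iMax} must not exceed the length of the ranked list.
#' @param params an \linkS4class{SVMParams}.
#' @param k folds (default 10).
#' @param seed fold-partition seed.
#' @param folds optional precomputed partition from
#'   \code{\link{makeStratifiedFolds}}.
#' @return an \linkS4class{IFSCurve}.
#' @export
runIFS <- function(x, ranked, iMin = 4L, iMax = 500L, step = 1L,
                   params = svmParams(), k = 10L, seed = 1L, folds = NULL) {
    genes <- if (is(ranked, "RankedFeatures")) ranking(ranked) else
        as.character(ranked)
    iMin <- as.integer(iMin); iMax <- as.integer(iMax); step <- as.integer(step)
    if (iMin < 1L) stop("iMin must be >= 1")
    if (iMax > length(genes))
        stop("iMax (", iMax, ") exceeds ranked-list length (", length(genes), ")")
    if (iMax < iMin) stop("iMax must be >= iMin")
    if (step < 1L) stop("step must be >= 1")
    sizes <- seq.int(iMin, iMax, by = step)
    if (is.null(folds)) folds <- makeStratifiedFolds(tissueLabels(x), k, seed)
    results <- lapply(sizes, function(i)
        crossValidate(x, genes[seq_len(i)], params = params, folds = folds))
    new("IFSCurve", sizes = sizes, results = results,
        foldId = attr(folds, "foldId") %||% "")
}

#' Select the optimal point of an IFS curve
#'
#' Returns the scan point with the highest cross-validated multiclass MCC;
#' exact ties are broken toward the smallest feature count (parsimony).
#'
#' @param curve an \linkS4class{IFSCurve}.
#' @param ranked optional \linkS4class{RankedFeatures} (or character vector)
#'   the curve was scanned over; when given, the optimal gene set is
#'   returned too.
#' @return list with \code{size} (optimal i), \code{result} (its
#'   \linkS4class{CVResult}) and, when \code{ranked} is supplied,
#'   \code{features} (the optimal top-i gene ids).
#' @export
selectOptimal <- function(curve, ranked = NULL) {
    stopifnot(is(curve, "IFSCurve"))
    if (!length(curve@sizes)) stop("curve is empty")
    mccs <- vapply(curve@results, mcc, numeric(1L))
    best <- which(mccs == max(mccs))[1L]  # sizes increasing: first = smallest
    out <- list(size = curve@sizes[best], result = curve@results[[best]])
    if (!is.null(ranked)) {
        genes <- if (is(ranked, "RankedFeatures")) ranking(ranked) else
            as.character(ranked)
        out$features <- genes[seq_len(out$size)]
    }
    out
}

#' Curve points as a data frame
#'
#' @param curve an \linkS4class{IFSCurve}.
#' @return data.frame with columns \code{i}, \code{MCC}, \code{TACC} and one
#'   \code{ACC_<tag>} column per tissue.
#' @export
ifsCurveTable <- function(curve) {
    stopifnot(is(curve, "IFSCurve"))
    accs <- t(vapply(curve@results, classAccuracy,
                     classAccuracy(curve@results[[1L]])))
    colnames(accs) <- paste0("ACC_", colnames(accs))
    data.frame(i = curve@sizes,
               MCC = vapply(curve@results, mcc, numeric(1L)),
               TACC = vapply(curve@results, tacc, numeric(1L)),
               accs, check.names = FALSE)
}

#' Write / read an IFS curve table
#'
#' TSV with columns i, MCC, TACC, ACC_<tag>... (N + 3 columns for N
#' tissues). \code{readIFSCurveTable} reads it back as the data frame
#' produced by \code{\link{ifsCurveTable}}.
#'
#' @param curve an \linkS4class{IFSCurve}.
#' @param path TSV path.
#' @return \code{writeIFSCurve}: \code{path}, invisibly;
#'   \code{readIFSCurveTable}: a data.frame.
#' @export
writeIFSCurve <- function(curve, path) {
    df <- ifsCurveTable(curve)
    num <- vapply(df, is.numeric, logical(1L)) & names(df) != "i"
    df[num] <- lapply(df[num], function(v) format(v, digits = 17, trim = TRUE))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeIFSCurve
#' @export
readIFSCurveTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            check.names = FALSE)
    if (!all(c("i", "MCC", "TACC") %in% colnames(df)))
        stop("not an IFS curve table: ", path)
    df
}

#' Plot an IFS curve
#'
#' Feature count on the x-axis against cross-validated multiclass MCC on the
#' y-axis, with the selected optimum highlighted.
#'
#' @param curve an \linkS4class{IFSCurve}.
#' @param path optional image path; \code{.pdf} opens a PDF device, anything
#'   else a PNG. When NULL, draws on the current device.
#' @return the optimum as returned by \code{\link{selectOptimal}},
#'   invisibly.
#' @export
plotIFSCurve <- function(curve, path = NULL) {
    opt <- selectOptimal(curve)
    if (!is.null(path)) {
        if (grepl("\\.pdf$", path, ignore.case = TRUE))
            grDevices::pdf(path, width = 7, height = 5)
        else grDevices::png(path, width = 900, height = 640)
        on.exit(grDevices::dev.off())
    }
    mccs <- vapply(curve@results, mcc, numeric(1L))
    graphics::plot(curve@sizes, mccs, type = "l", lwd = 1.5,
                   xlab = "Number of features", ylab = "MCC (10-fold CV)",
                   main = "Incremental feature selection",
                   xlim = range(curve@sizes))
    graphics::points(opt$size, mcc(opt$result), pch = 18, col = "red",
                     cex = 1.6)
    graphics::text(opt$size, mcc(opt$result),
                   labels = sprintf("i = %d, MCC = %.3f", opt$size,
                                    mcc(opt$result)),
                   pos = 1, col = "red", cex = 0.85)
    invisible(opt)
}
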
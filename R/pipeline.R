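#' Write a synthetic dataset to disk
#'
#' Materializes a generated dataset as the three plain-text artifacts the
#' file-based pipeline consumes: a GCT v1.2 expression matrix, a SAMPID/SMTS
#' label table, and a gene-role table recording the planted ground truth
#' (gene_id, role, home_tissue).
#'
#' @param spec a \linkS4class{SyntheticSpec} (or an already generated
#'   \linkS4class{TissueExpressionSet}).
#' @param dir output directory (created if needed).
#' @return invisibly, a named list of the three file paths (\code{gct},
#'   \code{labels}, \code{roles}).
#' @export
simulateToFiles <- function(spec, dir) {
    tes <- if (is(spec, "TissueExpressionSet")) spec else generateDataset(spec)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    paths <- list(gct = file.path(dir, "expression.gct"),
                  labels = file.path(dir, "labels.tsv"),
                  roles = file.path(dir, "gene_roles.tsv"))
    writeGCT(tes, paths$gct)
    writeSampleLabels(tissueLabels(tes), paths$labels)
    rd <- rowData(tes)
    roles <- data.frame(gene_id = rownames(tes),
                        role = as.character(rd$role),
                        home_tissue = as.character(rd$home_tissue))
    utils::write.table(roles, paths$roles, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(paths)
}

#' Load a dataset from a GCT matrix and a label table
#'
#' @param gctPath path to a GCT v1.2 file.
#' @param labelsPath path to a SAMPID/SMTS TSV; must label every sample of
#'   the matrix.
#' @return a \linkS4class{TissueExpressionSet}.
#' @export
readDataset <- function(gctPath, labelsPath) {
    m <- readGCT(gctPath)
    labels <- readSampleLabels(labelsPath)
    TissueExpressionSet(m, labels)
}

#' Run the full tissue-classification pipeline
#'
#' Executes the complete analysis on a training dataset: (1) drop tissues
#' below the minimum sample count, then drop genes expressed in no sample;
#' (2) discretize and rank all genes by greedy mRMR; (3) scan ranked
#' prefixes with the IFS harness under a single shared 10-fold partition;
#' (4) select the prefix with the highest cross-validated multiclass MCC;
#' (5) refit the SVM on the full training set with the optimal features and,
#' when an independent test set is supplied, evaluate it there (test samples
#' influence neither normalization nor training).
#'
#' @param train a \linkS4class{TissueExpressionSet} of training samples.
#' @param test optional independent \linkS4class{TissueExpressionSet}; its
#'   tissues must be a subset of the training tags.
#' @param minTissueSamples minimum per-tissue sample count (default 80).
#' @param alpha discretization width (see
#'   \code{\link{discretizeExpression}}).
#' @param criterion mRMR criterion, \code{"MID"} or \code{"MIQ"}.
#' @param iMin,iMax,step IFS scan range; \code{iMax} is clamped to the
#'   number of genes surviving the filters.
#' @param topN number of genes to mRMR-rank (default: \code{iMax}; ranking
#'   deeper than the scan needs is wasted work).
#' @param params an \linkS4class{SVMParams}.
#' @param k CV folds (default 10).
#' @param cvSeed fold-partition seed.
#' @param outDir optional run directory; when given, all artifacts are
#'   written there (ranked list, IFS curve TSV and PDF plot, optimal gene
#'   list, per-tissue CV and test reports, run log).
#' @return list with elements \code{data} (filtered training set),
#'   \code{ranked} (\linkS4class{RankedFeatures}), \code{curve}
#'   (\linkS4class{IFSCurve}), \code{optimal} (from
#'   \code{\link{selectOptimal}}, with features), \code{model} (the refitted
#'   \code{tissueSVM}) and, when \code{test} is given, \code{testResult}
#'   (a \linkS4class{CVResult}-shaped evaluation of the held-out samples).
#' @export
runPipeline <- function(train, test = NULL, minTissueSamples = 80L,
                        alpha = 1, criterion = "MID", iMin = 4L, iMax = 500L,
                        step = 1L, topN = NULL, params = svmParams(),
                        k = 10L, cvSeed = 1L, outDir = NULL) {
    stopifnot(is(train, "TissueExpressionSet"))
    train <- filterTissuesByMinSamples(train, minTissueSamples)
    train <- filterExpressedGenes(train)
    if (nrow(train) < 1L) stop("no expressed genes remain after filtering")

    iMax <- min(as.integer(iMax), nrow(train))
    if (is.null(topN)) topN <- iMax
    topN <- max(as.integer(topN), iMax)

    disc <- discretizeExpression(train, alpha = alpha)
    ranked <- rankFeaturesMRMR(disc, tissueLabels(train),
                               criterion = criterion, topN = topN)
    folds <- makeStratifiedFolds(tissueLabels(train), k, cvSeed)
    curve <- runIFS(train, ranked, iMin = iMin, iMax = iMax, step = step,
                    params = params, folds = folds)
    optimal <- selectOptimal(curve, ranked)
    model <- trainSVM(train, optimal$features, params)

    out <- list(data = train, ranked = ranked, curve = curve,
                optimal = optimal, model = model)
    if (!is.null(test)) {
        if (!all(tissueTags(test) %in% tissueTags(train)))
            stop("test tissues must be a subset of the training tags")
        pred <- predict(model, test)
        out$testResult <- confusionFromLabels(
            factor(as.character(tissueLabels(test)), levels = tissueTags(train)),
            pred, tags = tissueTags(train), foldId = "independent-test")
    }
    if (!is.null(outDir)) .writeRunDir(out, outDir, cvSeed, k)
    out
}

.writeRunDir <- function(res, outDir, cvSeed, k) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeRankedFeatures(res$ranked, file.path(outDir, "ranked_genes.tsv"))
    writeIFSCurve(res$curve, file.path(outDir, "ifs_curve.tsv"))
    plotIFSCurve(res$curve, file.path(outDir, "ifs_curve.pdf"))
    utils::write.table(
        data.frame(rank = seq_along(res$optimal$features),
                   gene_id = res$optimal$features),
        file.path(outDir, "optimal_genes.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    writeCVReport(res$optimal$result, file.path(outDir, "cv_report.tsv"))
    if (!is.null(res$testResult))
        writeCVReport(res$testResult, file.path(outDir, "test_report.tsv"))
    log <- c(sprintf("tissueIFS %s", as.character(utils::packageVersion("tissueIFS"))),
             sprintf("R %s", paste(R.version$major, R.version$minor, sep = ".")),
             sprintf("cv_seed\t%d", as.integer(cvSeed)),
             sprintf("k_folds\t%d", as.integer(k)),
             sprintf("fold_id\t%s", res$curve@foldId),
             sprintf("optimal_i\t%d", res$optimal$size),
             sprintf("optimal_mcc\t%.15g", mcc(res$optimal$result)),
             sprintf("optimal_tacc\t%.15g", tacc(res$optimal$result)))
    if (!is.null(res$testResult))
        log <- c(log, sprintf("test_mcc\t%.15g", mcc(res$testResult)),
                 sprintf("test_tacc\t%.15g", tacc(res$testResult)))
    writeLines(log, file.path(outDir, "run_log.txt"))
    invisible(outDir)
}
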
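#' Discretize an expression matrix into three states
#'
#' Per gene, values are mapped onto \{-1, 0, +1\} around the gene's own
#' mean: below \code{mean - alpha*sd} is -1, above \code{mean + alpha*sd} is
#' +1, and 0 in between (the standard categorical preprocessing of
#' mutual-information feature ranking applied to continuous expression
#' values). A constant gene has zero spread, so every value maps to 0.
#'
#' @param x a \linkS4class{TissueExpressionSet} or numeric genes-by-samples
#'   matrix.
#' @param alpha positive width multiplier of the central band (default 1).
#' @return a \linkS4class{DiscretizedExpression}.
#' @export
discretizeExpression <- function(x, alpha = 1) {
    m <- if (is(x, "TissueExpressionSet")) exprMatrix(x) else as.matrix(x)
    if (nrow(m) < 1L || ncol(m) < 1L) stop("matrix must be non-empty")
    if (alpha <= 0) stop("alpha must be > 0")
    mu <- rowMeans(m)
    sd <- apply(m, 1L, stats::sd)
    sd[is.na(sd)] <- 0
    lo <- mu - alpha * sd
    hi <- mu + alpha * sd
    st <- matrix(0L, nrow(m), ncol(m), dimnames = dimnames(m))
    st[m < lo] <- -1L
    st[m > hi] <- 1L
    new("DiscretizedExpression", states = st,
        thresholds = cbind(low = lo, high = hi), alpha = alpha)
}

# Plug-in mutual information (bits) between two integer-coded vectors with
# alphabet sizes na, nb. Codes must be in 1..na and 1..nb.
.miCodes <- function(a, b, na, nb) {
    n <- length(a)
    joint <- tabulate(a + na * (b - 1L), nbins = na * nb) / n
    pa <- tabulate(a, nbins = na) / n
    pb <- tabulate(b, nbins = nb) / n
    outer_p <- as.vector(pa %o% pb)
    nz <- joint > 0
    sum(joint[nz] * log2(joint[nz] / outer_p[nz]))
}

#' Mutual information between two discrete sequences
#'
#' Plug-in estimate over the empirical joint frequencies,
#' \eqn{\sum_{x,y} p(x,y) \log_2 \frac{p(x,y)}{p(x)p(y)}}, in bits; 0 log 0
#' terms contribute 0. Non-negative and symmetric; equals the marginal
#' entropy H(x) when \code{y = x}.
#'
#' @param x,y equal-length vectors of discrete values (any atomic type or
#'   factor).
#' @return a single non-negative numeric, in bits.
#' @examples
#' mutualInformation(rep(c("a", "b"), 50), rep(c("u", "v"), 50))  # 1 bit
#' @export
mutualInformation <- function(x, y) {
    if (length(x) != length(y)) stop("x and y must have equal length")
    if (length(x) < 1L) stop("sequences must be non-empty")
    fx <- factor(x); fy <- factor(y)
    .miCodes(as.integer(fx), as.integer(fy), nlevels(fx), nlevels(fy))
}

#' Greedy mRMR gene ranking
#'
#' Ranks genes by the minimum-redundancy maximum-relevance criterion:
#' relevance of a gene is its mutual information with the tissue label
#' (treated as one categorical variable over all tags), redundancy is its
#' mean mutual information with the already-selected genes. The first gene
#' maximizes relevance; each subsequent gene maximizes, over the non-selected
#' genes,
#' \itemize{
#'   \item \code{MID} (difference form, default):
#'     \eqn{MI(f; c) - \frac{1}{|S|}\sum_{s \in S} MI(f; s)}
#'   \item \code{MIQ} (quotient form):
#'     \eqn{MI(f; c) / \frac{1}{|S|}\sum_{s \in S} MI(f; s)}
#' }
#' Ties are broken by input gene order, so reruns are bit-identical. Each
#' pairwise mutual information is computed at most once: the per-candidate
#' redundancy sum is grown incrementally by one term (candidate vs the gene
#' selected in the previous step) per iteration.
#'
#' @param disc a \linkS4class{DiscretizedExpression} (see
#'   \code{\link{discretizeExpression}}).
#' @param labels tissue label per sample: a factor (e.g.
#'   \code{\link{tissueLabels}}) parallel to the columns of \code{disc}, with
#'   at least 2 represented classes.
#' @param criterion \code{"MID"} or \code{"MIQ"}.
#' @param topN number of genes to rank (default: all). Ranking stops after
#'   \code{topN} selections; the returned list then has length \code{topN}.
#' @return a \linkS4class{RankedFeatures}; scores are relevance for rank 1
#'   and the criterion value at selection time afterwards.
#' @export
rankFeaturesMRMR <- function(disc, labels, criterion = c("MID", "MIQ"),
                             topN = NULL) {
    stopifnot(is(disc, "DiscretizedExpression"))
    criterion <- match.arg(criterion)
    st <- disc@states
    nGenes <- nrow(st); nSamples <- ncol(st)
    if (nGenes < 1L) stop("at least one gene is required")
    labels <- factor(labels)
    labels <- droplevels(labels)
    if (length(labels) != nSamples)
        stop("labels must be parallel to the samples of the discretized matrix")
    if (nlevels(labels) < 2L)
        stop("at least 2 tissue classes are required for relevance ranking")
    if (is.null(topN)) topN <- nGenes
    topN <- min(as.integer(topN), nGenes)

    codes <- st + 2L  # states -1/0/1 -> 1/2/3
    cls <- as.integer(labels)
    nCls <- nlevels(labels)
    relevance <- vapply(seq_len(nGenes), function(g)
        .miCodes(codes[g, ], cls, 3L, nCls), numeric(1L))

    selected <- integer(topN)
    scores <- numeric(topN)
    remaining <- seq_len(nGenes)
    redSum <- numeric(nGenes)

    first <- remaining[which.max(relevance[remaining])]
    selected[1L] <- first
    scores[1L] <- relevance[first]
    remaining <- remaining[remaining != first]

    if (topN > 1L) {
        for (t in 2L:topN) {
            last <- selected[t - 1L]
            lastCodes <- codes[last, ]
            redSum[remaining] <- redSum[remaining] +
                vapply(remaining, function(g)
                    .miCodes(codes[g, ], lastCodes, 3L, 3L), numeric(1L))
            meanRed <- redSum[remaining] / (t - 1L)
            sc <- if (criterion == "MID")
                relevance[remaining] - meanRed
            else
                relevance[remaining] / pmax(meanRed, .Machine$double.eps)
            pick <- which.max(sc)
            selected[t] <- remaining[pick]
            scores[t] <- sc[pick]
            remaining <- remaining[-pick]
        }
    }

    ids <- rownames(st)
    if (is.null(ids)) ids <- as.character(seq_len(nGenes))
    new("RankedFeatures", ranking = ids[selected], scores = scores,
        criterion = criterion)
}

#' Write / read a ranked gene list
#'
#' Four-column TSV (rank, gene_id, score, criterion) so a ranking can be
#' produced once and fed to the incremental-feature-selection stage later.
#'
#' @param x a \linkS4class{RankedFeatures}.
#' @param path TSV path.
#' @return \code{writeRankedFeatures}: \code{path} invisibly;
#'   \code{readRankedFeatures}: a \linkS4class{RankedFeatures}.
#' @export
writeRankedFeatures <- function(x, path) {
    stopifnot(is(x, "RankedFeatures"))
    df <- data.frame(rank = seq_along(x@ranking), gene_id = x@ranking,
                     score = format(x@scores, digits = 17, trim = TRUE),
                     criterion = x@criterion)
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeRankedFeatures
#' @export
readRankedFeatures <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = c("integer", "character", "numeric",
                                           "character"))
    if (!identical(colnames(df), c("rank", "gene_id", "score", "criterion")))
        stop("not a ranked-feature table: ", path)
    df <- df[order(df$rank), ]
    new("RankedFeatures", ranking = df$gene_id, scores = df$score,
        criterion = unique(df$criterion)[1L])
}
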
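#' Cross-validate an externally supplied gene list
#'
#' Evaluates a fixed gene set — e.g. a published tissue-enriched gene list —
#' under exactly the same SVM and cross-validation harness as the mRMR/IFS
#' pipeline, so the resulting \linkS4class{CVResult} is directly comparable
#' with the pipeline's optimum. Given the same seed (or \code{folds}), the
#' fold partition is identical to the main run's.
#'
#' Genes absent from the matrix are dropped with a warning naming them;
#' evaluation proceeds on the overlap.
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @param genes character vector of gene ids (>= 1 must be present in
#'   \code{x}).
#' @param k,seed,params,folds as in \code{\link{crossValidate}}.
#' @return a \linkS4class{CVResult}.
#' @export
evaluateGeneList <- function(x, genes, k = 10L, seed = 1L,
                             params = svmParams(), folds = NULL) {
    stopifnot(is(x, "TissueExpressionSet"))
    genes <- unique(as.character(genes))
    present <- genes[genes %in% rownames(x)]
    absent <- setdiff(genes, present)
    if (!length(present))
        stop("none of the listed genes are present in the matrix")
    if (length(absent))
        warning(length(absent), " listed gene(s) absent from the matrix and dropped: ",
                paste(utils::head(absent, 10L), collapse = ", "))
    crossValidate(x, present, k = k, seed = seed, params = params,
                  folds = folds)
}

#' Read a gene list from a TSV file
#'
#' Accepts a one-column file of gene ids (with or without a header line
#' named \code{gene_id}) or a two-column (gene_id, source) table.
#'
#' @param path file path.
#' @return character vector of unique gene ids.
#' @export
readGeneList <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = FALSE, sep = "\t",
                            colClasses = "character")
    ids <- df[[1L]]
    if (length(ids) && ids[1L] %in% c("gene_id", "gene", "Name"))
        ids <- ids[-1L]
    unique(ids[nzchar(ids)])
}

# Vectorized Welch statistics of (group A vs group B) per gene.
# Cross-checked against stats::t.test in the test suite.
.welchRows <- function(m, inA) {
    a <- m[, inA, drop = FALSE]; b <- m[, !inA, drop = FALSE]
    na <- ncol(a); nb <- ncol(b)
    ma <- rowMeans(a); mb <- rowMeans(b)
    va <- rowSums((a - ma)^2) / (na - 1L)
    vb <- rowSums((b - mb)^2) / (nb - 1L)
    seA <- va / na; seB <- vb / nb
    se <- sqrt(seA + seB)
    t <- (ma - mb) / se
    df <- (seA + seB)^2 / (seA^2 / (na - 1L) + seB^2 / (nb - 1L))
    # both groups constant: equal means give t = 0 (no evidence), unequal
    # means give +/-Inf (complete separation)
    zero <- se == 0
    t[zero] <- sign(ma[zero] - mb[zero]) * Inf
    t[zero & ma == mb] <- 0
    df[zero] <- na + nb - 2L
    p2 <- 2 * stats::pt(-abs(t), df)
    p1 <- stats::pt(t, df, lower.tail = FALSE)
    data.frame(gene_id = rownames(m), t = t, df = df, p_two_sided = p2,
               p_over = p1, mean_tissue = ma, mean_rest = mb,
               row.names = NULL)
}

#' Rank genes by one-vs-rest Welch t-test for one tissue
#'
#' Welch (unequal-variance) two-sample t statistic of each gene between the
#' samples of one tissue and all other samples, ordered by t descending so
#' the most over-expressed genes in that tissue come first. The table
#' carries the t statistic, Welch degrees of freedom, the two-sided p-value
#' and the one-sided p-value for over-expression. The Welch form is used
#' because tissue sample sizes (and expression variances) are typically very
#' unequal.
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @param tissue a tissue tag of \code{x}; both the tissue and its
#'   complement need >= 2 samples.
#' @return data.frame (one row per gene, ranked by t descending) with
#'   columns gene_id, t, df, p_two_sided, p_over, mean_tissue, mean_rest.
#' @export
ttestRankTissue <- function(x, tissue) {
    stopifnot(is(x, "TissueExpressionSet"))
    labs <- tissueLabels(x)
    if (!tissue %in% levels(labs)) stop("unknown tissue tag: ", tissue)
    inA <- labs == tissue
    if (sum(inA) < 2L || sum(!inA) < 2L)
        stop("both the tissue and its complement need >= 2 samples")
    tab <- .welchRows(exprMatrix(x), inA)
    tab[order(-tab$t), , drop = FALSE]
}

#' Union of per-tissue top-k over-expressed genes
#'
#' For every tissue, ranks genes by the one-vs-rest Welch t statistic
#' (\code{\link{ttestRankTissue}}), keeps the top \code{topK} genes with
#' t > 0 (only over-expression qualifies a marker), and returns the union
#' with duplicates collapsed. The result records which tissues nominated
#' each gene; its size lies between \code{topK} (all rankings identical)
#' and \code{topK * n_tissues} (fully disjoint markers).
#'
#' @param x a \linkS4class{TissueExpressionSet} with >= 2 tissues.
#' @param topK genes kept per tissue (default 19).
#' @return data.frame with columns \code{gene_id}, \code{n_tissues} and
#'   \code{nominated_by} (comma-separated tags), ordered by first
#'   nomination; the per-tissue top lists are attached as attribute
#'   \code{"per_tissue"}.
#' @export
selectTTestGenes <- function(x, topK = 19L) {
    stopifnot(is(x, "TissueExpressionSet"))
    topK <- as.integer(topK)
    if (topK < 1L) stop("topK must be >= 1")
    if (topK > nrow(x))
        stop("topK (", topK, ") exceeds gene count (", nrow(x), ")")
    tags <- tissueTags(x)
    if (length(tags) < 2L) stop("at least 2 tissues are required")
    perTissue <- lapply(tags, function(tg) {
        tab <- ttestRankTissue(x, tg)
        tab <- tab[tab$t > 0, , drop = FALSE]
        utils::head(tab$gene_id, topK)
    })
    names(perTissue) <- tags
    all <- unlist(perTissue, use.names = FALSE)
    genes <- unique(all)
    nom <- lapply(genes, function(g)
        tags[vapply(perTissue, function(v) g %in% v, logical(1L))])
    out <- data.frame(gene_id = genes,
                      n_tissues = lengths(nom),
                      nominated_by = vapply(nom, paste, character(1L),
                                            collapse = ","))
    attr(out, "per_tissue") <- perTissue
    out
}
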
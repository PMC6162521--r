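#' Read a GCT v1.2 expression matrix
#'
#' Parses the tab-delimited GCT dialect shipped by bulk expression releases:
#' line 1 the version marker \code{#1.2}, line 2 the declared
#' \code{<n_genes>\\t<n_samples>} dimensions, line 3 the
#' \code{Name\\tDescription\\t<sample ids...>} header, then one gene per line.
#' Only v1.2 is accepted; the v1.3 dialect (extra metadata rows) is rejected
#' outright rather than guessed at. Declared dimensions must match the file
#' body exactly.
#'
#' @param path path to a GCT file.
#' @return numeric genes-by-samples matrix with gene ids as row names and
#'   sample ids as column names; the Description column is retained as the
#'   \code{"description"} attribute (named character vector).
#' @seealso \code{\link{writeGCT}}
#' @export
readGCT <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    perr <- function(lineno, text)
        stop(sprintf("GCT parse error at line %d: %s", lineno, text),
             call. = FALSE)
    if (length(lines) < 3L) perr(length(lines), "truncated file")
    if (identical(lines[1L], "#1.3"))
        perr(1L, "GCT v1.3 is not supported; only the v1.2 dialect is read")
    if (!identical(lines[1L], "#1.2"))
        perr(1L, sprintf("expected version marker '#1.2', found '%s'", lines[1L]))
    dims <- strsplit(lines[2L], "\t", fixed = TRUE)[[1L]]
    if (length(dims) != 2L || anyNA(suppressWarnings(as.integer(dims))))
        perr(2L, "dimensions line must be '<n_genes>\\t<n_samples>'")
    nGenes <- as.integer(dims[1L]); nSamples <- as.integer(dims[2L])
    hdr <- strsplit(lines[3L], "\t", fixed = TRUE)[[1L]]
    if (length(hdr) < 2L || hdr[1L] != "Name" || hdr[2L] != "Description")
        perr(3L, "header must start with 'Name\\tDescription'")
    sampleIds <- hdr[-(1:2)]
    if (length(sampleIds) != nSamples)
        perr(3L, sprintf("declared %d samples but header lists %d",
                         nSamples, length(sampleIds)))
    if (anyDuplicated(sampleIds))
        perr(3L, "duplicate sample identifiers")
    body <- lines[-(1:3)]
    body <- body[nzchar(body)]
    if (length(body) != nGenes)
        perr(length(lines), sprintf("declared %d genes but found %d data rows",
                                    nGenes, length(body)))
    parts <- strsplit(body, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(nf != nSamples + 2L)
    if (length(bad))
        perr(bad[1L] + 3L, sprintf("expected %d fields, found %d",
                                   nSamples + 2L, nf[bad[1L]]))
    geneIds <- vapply(parts, `[[`, character(1L), 1L)
    if (anyDuplicated(geneIds))
        perr(which(duplicated(geneIds))[1L] + 3L, "duplicate gene identifier")
    desc <- vapply(parts, `[[`, character(1L), 2L)
    vals <- suppressWarnings(
        vapply(parts, function(p) as.numeric(p[-(1:2)]), numeric(nSamples)))
    if (nSamples == 1L) vals <- matrix(vals, nrow = 1L)
    m <- t(vals)  # vapply returned samples x genes
    if (anyNA(m)) {
        badRow <- which(apply(is.na(m), 1L, any))[1L]
        perr(badRow + 3L, "non-numeric expression value")
    }
    dimnames(m) <- list(geneIds, sampleIds)
    names(desc) <- geneIds
    attr(m, "description") <- desc
    m
}

#' Write a GCT v1.2 expression matrix
#'
#' Inverse of \code{\link{readGCT}}: \code{readGCT(writeGCT(m, p))} returns
#' the same matrix at stored precision (values are written with full double
#' precision).
#'
#' @param x numeric genes-by-samples matrix with dimnames, or a
#'   \linkS4class{TissueExpressionSet} (its \code{"expr"} assay is written).
#' @param path output file path.
#' @param description optional per-gene description column (named or parallel
#'   character vector); defaults to the matrix's \code{"description"}
#'   attribute or \code{"na"}.
#' @return \code{path}, invisibly.
#' @export
writeGCT <- function(x, path, description = NULL) {
    if (is(x, "TissueExpressionSet")) x <- exprMatrix(x)
    if (is.null(rownames(x)) || is.null(colnames(x)))
        stop("matrix must carry gene and sample identifiers")
    if (is.null(description)) description <- attr(x, "description")
    if (is.null(description)) description <- rep("na", nrow(x))
    if (!is.null(names(description))) description <- description[rownames(x)]
    description[is.na(description) | !nzchar(description)] <- "na"
    con <- tryCatch(file(path, "w"),
                    error = function(e) stop("cannot write to ", path))
    on.exit(close(con))
    writeLines(c("#1.2", paste(nrow(x), ncol(x), sep = "\t"),
                 paste(c("Name", "Description", colnames(x)), collapse = "\t")),
               con)
    rows <- apply(x, 1L, function(v)
        paste(format(v, digits = 17, scientific = FALSE, trim = TRUE),
              collapse = "\t"))
    writeLines(paste(rownames(x), description, rows, sep = "\t"), con)
    invisible(path)
}

#' Read / write a sample-to-tissue label table
#'
#' Two-column tab-separated table with header \code{SAMPID\\tSMTS} (sample
#' identifier, tissue tag), the layout of cohort sample-attribute files.
#' Tissue-tag order is first appearance order in the file.
#'
#' @param path path to the TSV file.
#' @return \code{readSampleLabels}: a factor of tissue tags named by sample
#'   id, levels in canonical order.
#' @export
readSampleLabels <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    if (ncol(df) < 2L || !identical(colnames(df)[1:2], c("SAMPID", "SMTS")))
        stop("label table must have header 'SAMPID\\tSMTS'")
    if (anyDuplicated(df$SAMPID))
        stop("duplicate SAMPID: ",
             paste(unique(df$SAMPID[duplicated(df$SAMPID)]), collapse = ", "))
    if (any(!nzchar(df$SMTS))) stop("empty tissue tag in label table")
    out <- factor(df$SMTS, levels = unique(df$SMTS))
    names(out) <- df$SAMPID
    out
}

#' @rdname readSampleLabels
#' @param labels factor or character vector of tissue tags, named by sample
#'   id (e.g. from \code{\link{tissueLabels}}).
#' @return \code{writeSampleLabels}: \code{path}, invisibly.
#' @export
writeSampleLabels <- function(labels, path) {
    if (is.null(names(labels))) stop("labels must be named by sample id")
    df <- data.frame(SAMPID = names(labels), SMTS = as.character(labels))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' Keep genes expressed in at least one sample
#'
#' Retains exactly the genes with a non-zero value in at least one sample
#' ("not zero" means exactly 0.0, no epsilon — the expression unit is already
#' normalized and a literal zero is the non-expression code). Gene order and
#' retained values are unchanged; idempotent.
#'
#' @param x a \linkS4class{TissueExpressionSet} or a genes-by-samples matrix.
#' @return object of the same kind with all-zero genes removed (possibly 0
#'   genes).
#' @export
filterExpressedGenes <- function(x) {
    m <- if (is(x, "TissueExpressionSet")) exprMatrix(x) else x
    keep <- rowSums(m != 0) > 0L
    x[keep, , drop = FALSE]
}

#' Drop tissues with too few samples
#'
#' Removes every sample of any tissue contributing fewer than \code{minN}
#' samples, and drops those tags from the canonical tag order (the default 80
#' reflects the convention of excluding classes too small to cross-validate
#' stably). Idempotent.
#'
#' @param x a \linkS4class{TissueExpressionSet}.
#' @param minN minimum per-tissue sample count (default 80).
#' @return a \linkS4class{TissueExpressionSet} restricted to the retained
#'   tissues.
#' @export
filterTissuesByMinSamples <- function(x, minN = 80L) {
    stopifnot(is(x, "TissueExpressionSet"))
    sizes <- table(tissueLabels(x))
    keepTags <- names(sizes)[sizes >= minN]
    if (!length(keepTags))
        stop("all tissues have fewer than ", minN, " samples")
    out <- x[, as.character(tissueLabels(x)) %in% keepTags]
    colData(out)$tissue <- factor(as.character(colData(out)$tissue),
                                  levels = keepTags)
    out
}
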
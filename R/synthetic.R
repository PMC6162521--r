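#' GTEx-style tissue panel: 25 tissues and their sample counts
#'
#' The 25-tissue panel used throughout the package documentation and as the
#' generator default: tags T1..T25, tissue names, and the number of training
#' and independent-test samples each tissue contributes (training sizes range
#' from 83 for uterus to 1259 for brain; 8436 training and 3367 test samples
#' in total).
#'
#' @return data.frame with columns \code{tag}, \code{tissue}, \code{train},
#'   \code{test}.
#' @examples
#' head(gtexTissueTable())
#' sum(gtexTissueTable()$train)
#' @export
gtexTissueTable <- function() {
    data.frame(
        tag = paste0("T", 1:25),
        tissue = c("Adipose tissue", "Adrenal gland", "Blood", "Blood vessel",
                   "Brain", "Breast", "Colon", "Esophagus", "Heart", "Liver",
                   "Lung", "Muscle", "Nerve", "Ovary", "Pancreas", "Pituitary",
                   "Prostate", "Skin", "Small intestine", "Spleen", "Stomach",
                   "Testis", "Thyroid", "Uterus", "Vagina"),
        train = c(577L, 145L, 511L, 689L, 1259L, 214L, 345L, 686L, 412L, 119L,
                  320L, 430L, 304L, 97L, 171L, 103L, 106L, 890L, 88L, 104L,
                  192L, 172L, 323L, 83L, 96L),
        test = c(237L, 50L, 54L, 242L, 455L, 84L, 169L, 348L, 201L, 58L, 123L,
                 155L, 122L, 39L, 82L, 82L, 48L, 342L, 52L, 60L, 75L, 91L,
                 139L, 32L, 27L),
        stringsAsFactors = FALSE
    )
}

#' Specify a synthetic tissue-expression study
#'
#' Builds the parameter object consumed by \code{\link{generateDataset}}.
#' Defaults describe a study shaped like the 25-tissue bulk RNA-seq panel of
#' \code{\link{gtexTissueTable}} (unequal class sizes, 83..1259 samples per
#' tissue) with a log-normal RPKM-like background and two planted gene
#' populations:
#' \itemize{
#'   \item \emph{quantitative} genes — expressed (above \code{floor} > 0) in
#'     every tissue, but with per-tissue log-mean shifts of SD
#'     \code{effectSd}: the "quantitatively tissue-specific" signal the
#'     pipeline is built to recover;
#'   \item \emph{enriched} genes — high in one home tissue
#'     (\code{enrichmentFold}) and suppressed elsewhere
#'     (\code{dropFactor}, with a \code{zeroFraction} of non-home values set
#'     to exactly 0, so the expressed-gene filter has work to do).
#' }
#'
#' @param nTissues number of tissue classes (>= 2).
#' @param samplesPerTissue integer vector of per-tissue sample counts
#'   (optionally named with tissue tags); default the training sizes of
#'   \code{gtexTissueTable()}.
#' @param nQuantGenes,nEnrichedGenes,nNoiseGenes planted gene counts.
#' @param baseLogMean,baseLogSd background log-normal parameters (natural
#'   log scale).
#' @param effectSd SD of per-tissue log-mean shifts for quantitative genes.
#' @param enrichmentFold home-tissue fold elevation for enriched genes
#'   (>= 1).
#' @param dropFactor multiplier applied to enriched genes outside the home
#'   tissue, in [0, 1].
#' @param zeroFraction fraction of non-home enriched values zeroed exactly.
#' @param floor minimum value of quantitative genes (> 0).
#' @param seed integer RNG seed.
#' @return a \linkS4class{SyntheticSpec}.
#' @examples
#' syntheticSpec(nTissues = 3, samplesPerTissue = c(10, 12, 8),
#'               nQuantGenes = 5, nNoiseGenes = 50, seed = 1)
#' @export
syntheticSpec <- function(nTissues = 25L,
                          samplesPerTissue = gtexTissueTable()$train,
                          nQuantGenes = 30L,
                          nEnrichedGenes = 25L,
                          nNoiseGenes = 1500L,
                          baseLogMean = 1.0,
                          baseLogSd = 1.0,
                          effectSd = 1.0,
                          enrichmentFold = 50.0,
                          dropFactor = 0.01,
                          zeroFraction = 0.5,
                          floor = 0.01,
                          seed = 1L) {
    if (missing(nTissues) && !missing(samplesPerTissue))
        nTissues <- length(samplesPerTissue)
    if (length(samplesPerTissue) == 1L && nTissues > 1L)
        samplesPerTissue <- rep(samplesPerTissue, nTissues)
    spt <- as.integer(samplesPerTissue)
    names(spt) <- names(samplesPerTissue)
    new("SyntheticSpec",
        nTissues = as.integer(nTissues),
        samplesPerTissue = spt,
        nQuantGenes = as.integer(nQuantGenes),
        nEnrichedGenes = as.integer(nEnrichedGenes),
        nNoiseGenes = as.integer(nNoiseGenes),
        baseLogMean = as.numeric(baseLogMean),
        baseLogSd = as.numeric(baseLogSd),
        effectSd = as.numeric(effectSd),
        enrichmentFold = as.numeric(enrichmentFold),
        dropFactor = as.numeric(dropFactor),
        zeroFraction = as.numeric(zeroFraction),
        floor = as.numeric(floor),
        seed = as.integer(seed))
}

# Component sub-seeds: one base seed per dataset, sub-streams drawn in a
# fixed documented order (1 = tissue assignment, 2 = noise, 3 = quantitative,
# 4 = enriched) so adding or resizing a later gene class never perturbs the
# draws of an earlier one. Kept below 2^31 - 1.
.subSeed <- function(seed, k) {
    as.integer((as.double(seed) + k * 1000003) %% (.Machine$integer.max - 1L))
}

.lognorm <- function(n, meanlog, sdlog) exp(stats::rnorm(n, meanlog, sdlog))

#' Generate a synthetic tissue-expression dataset with planted structure
#'
#' Draws a genes-by-samples expression matrix under the generative model of
#' \code{\link{syntheticSpec}}. All values are non-negative and the dataset is
#' a pure function of the spec (bit-identical across calls).
#'
#' \describe{
#'   \item{noise genes}{one log-normal law (\code{baseLogMean},
#'     \code{baseLogSd}) for every sample regardless of tissue — no class
#'     information.}
#'   \item{quantitative genes}{per gene, each tissue receives a log-mean
#'     shift drawn once from N(0, \code{effectSd}^2); samples are drawn
#'     log-normally around the shifted mean and raised to at least
#'     \code{floor}, hence non-zero in every tissue.}
#'   \item{enriched genes}{background draws with the home tissue (assigned
#'     round-robin over the tag order) multiplied by \code{enrichmentFold}
#'     and all other tissues multiplied by \code{dropFactor}, after which a
#'     \code{zeroFraction} of the non-home values is set to exactly 0.}
#' }
#'
#' @param spec a \linkS4class{SyntheticSpec}.
#' @return a \linkS4class{TissueExpressionSet} whose \code{rowData} carries
#'   \code{role} (quantitative/enriched/noise) and \code{home_tissue} (NA for
#'   non-enriched genes); retrieve the role map with \code{\link{geneRoles}}.
#' @examples
#' spec <- syntheticSpec(nTissues = 3, samplesPerTissue = 8, nQuantGenes = 4,
#'                       nEnrichedGenes = 2, nNoiseGenes = 20, seed = 7)
#' tes <- generateDataset(spec)
#' table(geneRoles(tes))
#' @export
generateDataset <- function(spec) {
    validObject(spec)
    nT <- spec@nTissues
    spt <- spec@samplesPerTissue
    tags <- names(spt)
    if (is.null(tags)) tags <- paste0("T", seq_len(nT))
    nSamples <- sum(spt)
    tissue <- factor(rep(tags, times = spt), levels = tags)
    sampleIds <- sprintf("S%05d", seq_len(nSamples))

    nQ <- spec@nQuantGenes; nE <- spec@nEnrichedGenes; nN <- spec@nNoiseGenes
    geneIds <- c(if (nQ) sprintf("QGENE%04d", seq_len(nQ)),
                 if (nE) sprintf("EGENE%04d", seq_len(nE)),
                 if (nN) sprintf("NGENE%05d", seq_len(nN)))
    roles <- c(rep("quantitative", nQ), rep("enriched", nE), rep("noise", nN))

    blocks <- list()

    # stream 2: noise background
    if (nN > 0L) {
        set.seed(.subSeed(spec@seed, 2L))
        noise <- matrix(.lognorm(nN * nSamples, spec@baseLogMean,
                                 spec@baseLogSd), nrow = nN)
        blocks$noise <- noise
    }

    # stream 3: quantitative genes (tissue-shifted log-means, floored)
    if (nQ > 0L) {
        set.seed(.subSeed(spec@seed, 3L))
        shifts <- matrix(stats::rnorm(nQ * nT, 0, spec@effectSd), nrow = nQ)
        meanlog <- spec@baseLogMean + shifts[, as.integer(tissue), drop = FALSE]
        quant <- matrix(exp(stats::rnorm(nQ * nSamples, as.vector(meanlog),
                                         spec@baseLogSd)), nrow = nQ)
        quant <- pmax(quant, spec@floor)
        blocks$quant <- quant
    }

    # stream 4: enriched genes (home tissue round-robin over tag order)
    home <- character(0L)
    if (nE > 0L) {
        set.seed(.subSeed(spec@seed, 4L))
        home <- tags[((seq_len(nE) - 1L) %% nT) + 1L]
        enr <- matrix(.lognorm(nE * nSamples, spec@baseLogMean,
                               spec@baseLogSd), nrow = nE)
        homeMask <- outer(home, as.character(tissue), `==`)
        enr <- enr * ifelse(homeMask, spec@enrichmentFold, spec@dropFactor)
        zero <- !homeMask &
            matrix(stats::runif(nE * nSamples) < spec@zeroFraction, nrow = nE)
        enr[zero] <- 0
        blocks$enr <- enr
    }

    expr <- matrix(numeric(0L), nrow = 0L, ncol = nSamples)
    ord <- list(blocks$quant, blocks$enr, blocks$noise)
    expr <- do.call(rbind, c(list(expr), ord[!vapply(ord, is.null, logical(1L))]))
    dimnames(expr) <- list(geneIds, sampleIds)

    rd <- DataFrame(role = roles,
                    home_tissue = c(rep(NA_character_, nQ), home,
                                    rep(NA_character_, nN)),
                    row.names = geneIds)
    tes <- TissueExpressionSet(expr, tissue, tags = tags, rowData = rd)
    metadata(tes)$spec_seed <- spec@seed
    tes
}

#' Stratified train/test split
#'
#' Splits a dataset into disjoint train and test subsets, sampling a fixed
#' fraction of every tissue independently (mirroring the construction of an
#' independent test set from later additions to a cohort). Every tissue keeps
#' at least one sample on each side.
#'
#' @param x a \linkS4class{TissueExpressionSet}; every tissue needs >= 2
#'   samples.
#' @param testFraction fraction of each tissue assigned to the test set,
#'   in (0, 1). The per-tissue test count is \code{round(testFraction * n)},
#'   clamped to [1, n - 1].
#' @param seed integer seed; the split is deterministic given it.
#' @return list with elements \code{train} and \code{test}, both
#'   \linkS4class{TissueExpressionSet}s over the full gene set.
#' @examples
#' tes <- generateDataset(syntheticSpec(nTissues = 3, samplesPerTissue = 8,
#'     nQuantGenes = 2, nEnrichedGenes = 0, nNoiseGenes = 10, seed = 1))
#' sp <- splitTrainTest(tes, 0.25, seed = 7)
#' ncol(sp$test)
#' @export
splitTrainTest <- function(x, testFraction, seed = 1L) {
    stopifnot(is(x, "TissueExpressionSet"))
    if (testFraction <= 0 || testFraction >= 1)
        stop("testFraction must lie strictly between 0 and 1")
    labs <- tissueLabels(x)
    sizes <- table(labs)
    if (any(sizes < 2L))
        stop("every tissue needs >= 2 samples to split; too small: ",
             paste(names(sizes)[sizes < 2L], collapse = ", "))
    set.seed(seed)
    testIdx <- unlist(lapply(levels(labs), function(tg) {
        idx <- which(labs == tg)
        nTest <- min(length(idx) - 1L, max(1L, round(testFraction * length(idx))))
        sample(idx, nTest)
    }), use.names = FALSE)
    testIdx <- sort(testIdx)
    list(train = x[, setdiff(seq_len(ncol(x)), testIdx)],
         test = x[, testIdx])
}
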
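# Independent oracles and small fixture builders shared across the suite.
# Every oracle recomputes its quantity by a route different from the
# package implementation it is used to check.

# Classical binary Matthews correlation coefficient from confusion counts.
binaryMCC <- function(tp, fp, fn, tn) {
    num <- tp * tn - fp * fn
    den <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    if (den == 0) return(0)
    num / den
}

# Plug-in mutual information via the entropy identity H(x) + H(y) - H(x, y)
# (the package sums joint/marginal ratios instead).
entropyMI <- function(x, y) {
    H <- function(v) {
        p <- table(v) / length(v)
        -sum(p * log2(p))
    }
    H(x) + H(y) - H(paste(x, y, sep = "\r"))
}

# Brute-force greedy mRMR that recomputes every mutual information from
# scratch at every step, with no caching and no incremental redundancy sums.
bruteMRMR <- function(stateMat, cls, criterion = "MID") {
    nGenes <- nrow(stateMat)
    rel <- vapply(seq_len(nGenes), function(g)
        entropyMI(stateMat[g, ], cls), numeric(1))
    sel <- integer(0)
    rem <- seq_len(nGenes)
    while (length(rem) > 0) {
        if (length(sel) == 0) {
            sc <- rel[rem]
        } else {
            sc <- vapply(rem, function(g) {
                red <- mean(vapply(sel, function(s)
                    entropyMI(stateMat[g, ], stateMat[s, ]), numeric(1)))
                if (criterion == "MID") rel[g] - red
                else rel[g] / max(red, .Machine$double.eps)
            }, numeric(1))
        }
        pick <- rem[which.max(sc)]
        sel <- c(sel, pick)
        rem <- rem[rem != pick]
    }
    sel
}

# Minimal TissueExpressionSet from a bare matrix and a label vector.
tinyTes <- function(m, tissue, tags = NULL) {
    if (is.null(rownames(m))) rownames(m) <- paste0("g", seq_len(nrow(m)))
    if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
    TissueExpressionSet(m, tissue, tags = tags)
}

# Label-free random dataset: every gene log-normal, no class information.
noiseTes <- function(nGenes, nTissues, perTissue, seed) {
    generateDataset(syntheticSpec(
        nTissues = nTissues, samplesPerTissue = perTissue,
        nQuantGenes = 0L, nEnrichedGenes = 0L, nNoiseGenes = nGenes,
        seed = seed))
}

# Random truth/prediction label pair over k classes.
randomLabelPair <- function(n, k, seed) {
    set.seed(seed)
    tags <- paste0("c", seq_len(k))
    list(truth = factor(sample(tags, n, replace = TRUE), levels = tags),
         pred = factor(sample(tags, n, replace = TRUE), levels = tags),
         tags = tags)
}
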
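test_that("invalid specs are rejected with the offending field named", {
    expect_error(syntheticSpec(nTissues = 1, samplesPerTissue = 5), "nTissues")
    expect_error(syntheticSpec(nTissues = 3, samplesPerTissue = c(5, 5)),
                 "samplesPerTissue")
    expect_error(syntheticSpec(nTissues = 2, samplesPerTissue = c(5, 0)),
                 "samplesPerTissue")
    expect_error(syntheticSpec(nTissues = 2, samplesPerTissue = 5,
                               nQuantGenes = 3, floor = 0), "floor")
    expect_error(syntheticSpec(nTissues = 2, samplesPerTissue = 5,
                               baseLogSd = 0), "baseLogSd")
    expect_error(syntheticSpec(nTissues = 2, samplesPerTissue = 5,
                               effectSd = -1), "effectSd")
    expect_error(syntheticSpec(nTissues = 2, samplesPerTissue = 5,
                               enrichmentFold = 0.5), "enrichmentFold")
})

spec5 <- syntheticSpec(nTissues = 5, samplesPerTissue = 12, nQuantGenes = 8,
                       nEnrichedGenes = 6, nNoiseGenes = 40, effectSd = 1,
                       seed = 42)

test_that("generation is deterministic, non-negative and fully annotated", {
    a <- generateDataset(spec5)
    b <- generateDataset(spec5)
    expect_identical(exprMatrix(a), exprMatrix(b))
    expect_identical(tissueLabels(a), tissueLabels(b))
    expect_true(all(exprMatrix(a) >= 0))
    expect_length(tissueTags(a), 5L)
    expect_false(anyNA(tissueLabels(a)))
    roles <- geneRoles(a)
    counts <- table(roles)
    expect_identical(as.integer(counts[c("quantitative", "enriched", "noise")]),
                     c(8L, 6L, 40L))
    expect_identical(sort(names(roles)), sort(rownames(a)))
})

test_that("quantitative genes are non-zero everywhere; enriched genes carry exact zeros off-home", {
    tes <- generateDataset(spec5)
    roles <- geneRoles(tes)
    m <- exprMatrix(tes)
    expect_true(all(m[roles == "quantitative", ] > 0))
    home <- enrichedHome(tes)
    # round-robin assignment: 6 enriched genes over 5 tissues
    expect_identical(unname(home), tissueTags(tes)[c(1:5, 1)])
    enr <- m[names(home), , drop = FALSE]
    labs <- as.character(tissueLabels(tes))
    for (i in seq_len(nrow(enr))) {
        offHome <- labs != home[i]
        expect_true(any(enr[i, offHome] == 0))
        expect_true(all(enr[i, !offHome] > 0))
        # home tissue strongly elevated relative to suppressed background
        expect_gt(mean(enr[i, !offHome]), mean(enr[i, offHome]))
    }
})

test_that("no planted signal means chance-level downstream classification", {
    tes <- generateDataset(syntheticSpec(
        nTissues = 4, samplesPerTissue = 20, nQuantGenes = 0,
        nEnrichedGenes = 0, nNoiseGenes = 60, effectSd = 0, seed = 11))
    cv <- crossValidate(tes, rownames(tes)[1:10], k = 10, seed = 1)
    expect_lt(abs(mcc(cv)), 0.1)
})

test_that("stratified split honors fractions, disjointness and determinism", {
    tes <- generateDataset(syntheticSpec(
        nTissues = 5, samplesPerTissue = 40, nQuantGenes = 2,
        nEnrichedGenes = 0, nNoiseGenes = 10, seed = 2))
    sp <- splitTrainTest(tes, 0.25, seed = 7)
    expect_identical(as.integer(table(tissueLabels(sp$test))), rep(10L, 5))
    expect_identical(as.integer(table(tissueLabels(sp$train))), rep(30L, 5))
    expect_length(intersect(colnames(sp$train), colnames(sp$test)), 0L)
    expect_setequal(c(colnames(sp$train), colnames(sp$test)), colnames(tes))
    expect_identical(rownames(sp$train), rownames(tes))

    sp2 <- splitTrainTest(tes, 0.25, seed = 7)
    expect_identical(colnames(sp2$test), colnames(sp$test))

    tiny <- generateDataset(syntheticSpec(
        nTissues = 3, samplesPerTissue = 2, nQuantGenes = 0,
        nEnrichedGenes = 0, nNoiseGenes = 5, seed = 1))
    sp3 <- splitTrainTest(tiny, 0.5, seed = 1)
    expect_identical(as.integer(table(tissueLabels(sp3$test))), rep(1L, 3))
    expect_identical(as.integer(table(tissueLabels(sp3$train))), rep(1L, 3))

    one <- tiny[, c(1, 3, 4, 5, 6)]  # tissue 1 left with a single sample
    expect_error(splitTrainTest(one, 0.5, seed = 1), "2 samples")
})

test_that("planted-signal strength monotonically improves recoverable MCC", {
    meanMCC <- function(effectSd) {
        mean(vapply(1:5, function(s) {
            tes <- generateDataset(syntheticSpec(
                nTissues = 5, samplesPerTissue = 16, nQuantGenes = 8,
                nEnrichedGenes = 0, nNoiseGenes = 40, effectSd = effectSd,
                seed = 100 + s))
            quant <- names(geneRoles(tes))[geneRoles(tes) == "quantitative"]
            mcc(evaluateGeneList(tes, quant, k = 4, seed = 1,
                                 params = svmParams(logTransform = TRUE)))
        }, numeric(1)))
    }
    m0 <- meanMCC(0); m1 <- meanMCC(0.5); m2 <- meanMCC(1.5)
    expect_lte(m0, m1)
    expect_lte(m1, m2)
})
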
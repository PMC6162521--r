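test_that("evaluating the full gene list equals full-feature cross-validation", {
    tes <- generateDataset(syntheticSpec(
        nTissues = 4, samplesPerTissue = 15, nQuantGenes = 6,
        nEnrichedGenes = 0, nNoiseGenes = 20, effectSd = 1.5, seed = 14))
    a <- evaluateGeneList(tes, rownames(tes), k = 5, seed = 3)
    b <- crossValidate(tes, rownames(tes), k = 5, seed = 3)
    expect_identical(confusion(a), confusion(b))
    expect_identical(mcc(a), mcc(b))
    # bit-for-bit reproducible with the same seed
    expect_identical(confusion(evaluateGeneList(tes, rownames(tes), k = 5,
                                                seed = 3)), confusion(a))
})

test_that("unknown genes are dropped with a warning naming them", {
    tes <- generateDataset(syntheticSpec(
        nTissues = 3, samplesPerTissue = 10, nQuantGenes = 4,
        nEnrichedGenes = 0, nNoiseGenes = 6, effectSd = 2, seed = 15))
    genes <- c(rownames(tes)[1:8], "GHOST1", "GHOST2")
    expect_warning(res <- evaluateGeneList(tes, genes, k = 5, seed = 1),
                   "GHOST1, GHOST2")
    expect_identical(sum(confusion(res)), ncol(tes))
    expect_error(evaluateGeneList(tes, c("GHOST1", "GHOST2")),
                 "none of the listed genes")
})

test_that("planted quantitative genes beat equal-sized random gene lists", {
    diffs <- vapply(1:5, function(s) {
        tes <- generateDataset(syntheticSpec(
            nTissues = 5, samplesPerTissue = 16, nQuantGenes = 8,
            nEnrichedGenes = 0, nNoiseGenes = 60, effectSd = 1, seed = 50 + s))
        roles <- geneRoles(tes)
        quant <- names(roles)[roles == "quantitative"]
        set.seed(s)
        rand <- sample(names(roles)[roles == "noise"], length(quant))
        p <- svmParams(logTransform = TRUE)
        mcc(evaluateGeneList(tes, quant, k = 5, seed = 1, params = p)) -
            mcc(evaluateGeneList(tes, rand, k = 5, seed = 1, params = p))
    }, numeric(1))
    expect_gt(mean(diffs), 0)
    expect_true(all(diffs >= 0))
})

test_that("Welch statistics match the reference t-test gene by gene", {
    set.seed(23)
    m <- matrix(exp(rnorm(15 * 20)), 15, 20,
                dimnames = list(paste0("g", 1:15), paste0("s", 1:20)))
    tes <- tinyTes(m, rep(c("a", "b", "c"), c(6, 7, 7)))
    tab <- ttestRankTissue(tes, "a")
    expect_identical(sort(tab$gene_id), sort(rownames(m)))
    expect_false(is.unsorted(rev(tab$t)))
    inA <- rep(c(TRUE, FALSE), c(6, 14))
    for (g in rownames(m)) {
        ref <- t.test(m[g, inA], m[g, !inA])
        row <- tab[tab$gene_id == g, ]
        expect_equal(row$t, unname(ref$statistic), tolerance = 1e-12)
        expect_equal(row$df, unname(ref$parameter), tolerance = 1e-12)
        expect_equal(row$p_two_sided, ref$p.value, tolerance = 1e-12)
    }
})

test_that("hand-sized Welch case and degenerate genes behave as derived", {
    # group means 10 vs 2, equal SD pattern, n = 5 each
    a <- c(9, 9.5, 10, 10.5, 11); b <- a - 8
    m <- rbind(marker = c(a, b), flat = rep(3, 10))
    colnames(m) <- paste0("s", 1:10)
    tes <- tinyTes(m, rep(c("hi", "lo"), each = 5))
    tab <- ttestRankTissue(tes, "hi")
    sa <- var(a) / 5
    tOracle <- (mean(a) - mean(b)) / sqrt(2 * sa)
    expect_equal(tab$t[tab$gene_id == "marker"], tOracle, tolerance = 1e-12)
    expect_identical(tab$t[tab$gene_id == "flat"], 0)
    expect_error(ttestRankTissue(tes, "nowhere"), "unknown tissue")
})

test_that("a planted enriched gene tops its home tissue's ranking", {
    tes <- generateDataset(syntheticSpec(
        nTissues = 4, samplesPerTissue = 12, nQuantGenes = 0,
        nEnrichedGenes = 4, nNoiseGenes = 30, enrichmentFold = 50, seed = 33))
    home <- enrichedHome(tes)
    for (g in names(home)) {
        tab <- ttestRankTissue(tes, home[[g]])
        expect_identical(tab$gene_id[1], g)
    }
})

test_that("location shifts move t only when applied to one group", {
    set.seed(41)
    m <- matrix(runif(5 * 16, 1, 3), 5, 16,
                dimnames = list(paste0("g", 1:5), paste0("s", 1:16)))
    tes <- tinyTes(m, rep(c("a", "b"), each = 8))
    base <- ttestRankTissue(tes, "a")
    shifted <- ttestRankTissue(tinyTes(m + 5, rep(c("a", "b"), each = 8)), "a")
    expect_equal(shifted$t[order(shifted$gene_id)],
                 base$t[order(base$gene_id)], tolerance = 1e-9)
    mUp <- m; mUp[, 1:8] <- mUp[, 1:8] + 5  # shift group a only
    up <- ttestRankTissue(tinyTes(mUp, rep(c("a", "b"), each = 8)), "a")
    expect_true(all(up$t[order(up$gene_id)] > base$t[order(base$gene_id)]))
})

test_that("disjoint per-tissue markers union to exactly topK x nTissues genes", {
    nT <- 25; perT <- 4; topK <- 19
    nMarkers <- nT * topK
    labs <- rep(paste0("T", 1:nT), each = perT)
    jitter <- rep(c(0, 0.01, -0.01, 0.02), length.out = nT * perT)
    m <- matrix(1 + rep(jitter, each = nMarkers), nMarkers, nT * perT)
    rownames(m) <- paste0("mk", seq_len(nMarkers))
    colnames(m) <- paste0("s", seq_len(nT * perT))
    for (t in seq_len(nT)) {
        rows <- ((t - 1) * topK + 1):(t * topK)
        m[rows, labs == paste0("T", t)] <- m[rows, labs == paste0("T", t)] + 10
    }
    tes <- tinyTes(m, labs)
    sel <- selectTTestGenes(tes, topK = topK)
    expect_identical(nrow(sel), 475L)
    expect_true(all(sel$n_tissues == 1L))
    expect_setequal(sel$gene_id, rownames(m))
})

test_that("tissues with identical rankings collapse the union to topK genes", {
    # tissues A and B carry identical sample values; their one-vs-rest
    # rankings coincide, so the union over all three tissues is one top list
    block <- matrix(c(10, 11, 12, 9, 13,
                      20, 21, 19, 22, 18,
                      5, 6, 4, 5.5, 6.5), 3, 5, byrow = TRUE)
    m <- cbind(block, block, matrix(1, 3, 5) + seq(0, 0.4, 0.1))
    rownames(m) <- paste0("g", 1:3)
    colnames(m) <- paste0("s", 1:15)
    tes <- tinyTes(m, rep(c("A", "B", "C"), each = 5))
    sel <- selectTTestGenes(tes, topK = 3)
    expect_identical(nrow(sel), 3L)
    expect_true(all(sel$n_tissues == 2L))  # nominated by both A and B
})

test_that("the union equals a brute-force per-tissue recomputation", {
    set.seed(61)
    m <- matrix(exp(rnorm(30 * 18)), 30, 18,
                dimnames = list(paste0("g", 1:30), paste0("s", 1:18)))
    labs <- rep(c("x", "y", "z"), each = 6)
    tes <- tinyTes(m, labs)
    topK <- 5
    sel <- selectTTestGenes(tes, topK = topK)
    oracle <- unique(unlist(lapply(c("x", "y", "z"), function(tg) {
        ts <- vapply(rownames(m), function(g)
            unname(t.test(m[g, labs == tg], m[g, labs != tg])$statistic),
            numeric(1))
        ts <- ts[ts > 0]
        names(sort(ts, decreasing = TRUE))[seq_len(min(topK, length(ts)))]
    })))
    expect_setequal(sel$gene_id, oracle)
    expect_gte(nrow(sel), topK)
    expect_lte(nrow(sel), topK * 3)
    expect_error(selectTTestGenes(tes, topK = 31), "exceeds gene count")
})
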
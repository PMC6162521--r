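test_that("three-state discretization matches hand-computed thresholds", {
    # values (0, 0, 0, 100): mean 25, sd 50 -> band [-25, 75]
    m <- matrix(c(0, 0, 0, 100), 1, 4,
                dimnames = list("g1", paste0("s", 1:4)))
    d <- discretizeExpression(m, alpha = 1)
    expect_identical(unname(states(d)[1, ]), c(0L, 0L, 0L, 1L))
    expect_equal(unname(d@thresholds[1, ]), c(-25, 75))

    # constant gene: zero spread, everything central
    dc <- discretizeExpression(matrix(7, 1, 5, dimnames = list("g", 1:5)))
    expect_true(all(states(dc) == 0L))

    # enormous alpha: the band swallows every value
    dw <- discretizeExpression(matrix(rnorm(40), 4, 10,
        dimnames = list(paste0("g", 1:4), paste0("s", 1:10))), alpha = 1e9)
    expect_true(all(states(dw) == 0L))

    expect_error(discretizeExpression(m, alpha = 0), "alpha")
})

test_that("mutual information matches closed forms and the plug-in sum", {
    # constant x: independent of anything
    expect_identical(mutualInformation(rep(1, 50), rbinom(50, 1, 0.5)), 0)
    # y = x uniform over two symbols: exactly 1 bit
    x <- rep(c("a", "b"), 100)
    expect_equal(mutualInformation(x, x), 1.0, tolerance = 1e-15)
    # fixed joint table ("a","u"):4 ("a","v"):1 ("b","u"):1 ("b","v"):4
    xs <- c(rep("a", 5), rep("b", 5))
    ys <- c(rep("u", 4), "v", "u", rep("v", 4))
    pj <- c(0.4, 0.1, 0.1, 0.4)
    px <- c(0.5, 0.5); py <- c(0.5, 0.5)
    direct <- sum(pj * log2(pj / c(px[1] * py[1], px[1] * py[2],
                                   px[2] * py[1], px[2] * py[2])))
    expect_equal(mutualInformation(xs, ys), direct, tolerance = 1e-15)
    expect_error(mutualInformation(1:3, 1:4), "equal length")
})

test_that("MI is symmetric and non-negative on random sequence pairs", {
    set.seed(31)
    for (i in 1:200) {
        x <- sample(1:3, 40, replace = TRUE)
        y <- sample(letters[1:4], 40, replace = TRUE)
        v <- mutualInformation(x, y)
        expect_gte(v, 0)
        expect_equal(v, mutualInformation(y, x), tolerance = 1e-14)
        expect_equal(v, entropyMI(x, y), tolerance = 1e-12)
    }
})

test_that("a single gene is ranked first with its relevance as score", {
    m <- matrix(c(1, 1, 10, 10), 1, 4, dimnames = list("only", paste0("s", 1:4)))
    d <- discretizeExpression(m)
    r <- rankFeaturesMRMR(d, factor(c("a", "a", "b", "b")))
    expect_identical(ranking(r), "only")
    expect_equal(unname(featureScores(r)),
                 mutualInformation(states(d)[1, ], c("a", "a", "b", "b")))
})

test_that("a label-carrying gene outranks label-independent noise", {
    for (s in 1:10) {
        set.seed(s)
        cls <- factor(rep(c("a", "b", "c"), each = 20))
        planted <- as.integer(cls) * 10          # states follow the label
        noise <- matrix(runif(20 * 60), 20, 60)  # label-independent
        m <- rbind(planted, noise)
        rownames(m) <- c("planted", paste0("n", 1:20))
        colnames(m) <- paste0("s", 1:60)
        r <- rankFeaturesMRMR(discretizeExpression(m), cls)
        expect_identical(ranking(r)[1], "planted")
    }
})

test_that("greedy ranking equals a brute-force greedy that recomputes every MI", {
    for (s in 1:8) {
        set.seed(200 + s)
        nGenes <- sample(4:8, 1)
        m <- matrix(exp(rnorm(nGenes * 60)), nGenes, 60,
                    dimnames = list(paste0("g", seq_len(nGenes)),
                                    paste0("s", 1:60)))
        cls <- factor(sample(c("a", "b", "c"), 60, replace = TRUE))
        d <- discretizeExpression(m)
        for (crit in c("MID", "MIQ")) {
            r <- rankFeaturesMRMR(d, cls, criterion = crit)
            oracle <- bruteMRMR(states(d), as.character(cls), criterion = crit)
            expect_identical(ranking(r), rownames(m)[oracle])
        }
    }
})

test_that("ranking is a deterministic permutation with argmax-relevance head", {
    set.seed(55)
    m <- matrix(exp(rnorm(12 * 45)), 12, 45,
                dimnames = list(paste0("g", 1:12), paste0("s", 1:45)))
    cls <- factor(sample(c("x", "y", "z"), 45, replace = TRUE))
    d <- discretizeExpression(m)
    r1 <- rankFeaturesMRMR(d, cls)
    r2 <- rankFeaturesMRMR(d, cls)
    expect_identical(ranking(r1), ranking(r2))
    expect_setequal(ranking(r1), rownames(m))
    rel <- vapply(seq_len(12), function(g)
        mutualInformation(states(d)[g, ], as.character(cls)), numeric(1))
    expect_identical(ranking(r1)[1], rownames(m)[which.max(rel)])
    # topN truncates the list but not the head
    r3 <- rankFeaturesMRMR(d, cls, topN = 5)
    expect_identical(ranking(r3), ranking(r1)[1:5])
})

test_that("a duplicated gene is pushed away from its twin by the redundancy penalty", {
    set.seed(17)
    n <- 300
    cls <- sample(1:3, n, replace = TRUE)
    flip <- function(v, p) ifelse(runif(n) < p, sample(1:3, n, TRUE), v)
    g1 <- flip(cls, 0.1)
    g3 <- flip(cls, 0.1)  # informative but independent of g1 given the class
    m <- rbind(g1 = g1 * 10, g2 = g1 * 10, g3 = g3 * 10)
    colnames(m) <- paste0("s", 1:n)
    r <- rankFeaturesMRMR(discretizeExpression(m), factor(cls),
                          criterion = "MID")
    expect_identical(ranking(r)[1], "g1")   # ties to input order
    expect_identical(ranking(r)[2], "g3")   # twin g2 deferred
})

test_that("single-class labels and empty matrices are rejected", {
    m <- matrix(1:8, 2, 4, dimnames = list(c("a", "b"), paste0("s", 1:4)))
    d <- discretizeExpression(m)
    expect_error(rankFeaturesMRMR(d, factor(rep("one", 4))), "2 tissue classes")
    expect_error(rankFeaturesMRMR(d, factor(c("a", "b"))), "parallel")
})

test_that("ranked lists survive the TSV round trip", {
    set.seed(3)
    m <- matrix(exp(rnorm(6 * 30)), 6, 30,
                dimnames = list(paste0("g", 1:6), paste0("s", 1:30)))
    cls <- factor(sample(c("a", "b"), 30, replace = TRUE))
    r <- rankFeaturesMRMR(discretizeExpression(m), cls)
    p <- tempfile(fileext = ".tsv")
    writeRankedFeatures(r, p)
    back <- readRankedFeatures(p)
    expect_identical(ranking(back), ranking(r))
    expect_equal(unname(featureScores(back)), unname(featureScores(r)),
                 tolerance = 1e-15)
    expect_identical(back@criterion, "MID")
})
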
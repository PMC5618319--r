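## a PCAModel with prescribed scores, for gap-logic tests
scoresOnlyModel <- function(Tmat) {
    K <- ncol(Tmat)
    new("PCAModel", scores = Tmat,
        loadings = diag(1, max(K, 2), K),
        explainedVar = rev(sort(colSums(Tmat^2))) / (nrow(Tmat) - 1),
        rank = as.integer(K))
}

test_that("componentGap is the nearest-neighbor score gap", {
    m <- scoresOnlyModel(cbind(c(10, 0, 1), c(0, 0, 0)))
    expect_equal(componentGap(m, 1, 1), 9)
    expect_equal(componentGap(m, 2, 1), 1)
    expect_equal(componentGap(m, 1, 2), 0)
    expect_error(componentGap(m, 1, 5), "out of range")
})

test_that("duplicate strains have zero gap on every component", {
    set.seed(2)
    Tmat <- matrix(rnorm(8), 4, 2)
    Tmat[4, ] <- Tmat[2, ]
    m <- scoresOnlyModel(Tmat)
    expect_equal(componentGap(m, 2, 1), 0)
    expect_equal(componentGap(m, 4, 2), 0)
})

test_that("componentGap and scoresOverview match a brute-force loop", {
    set.seed(23)
    Tmat <- matrix(rnorm(6 * 5), 6, 5,
                   dimnames = list(paste0("s", 1:6), NULL))
    m <- scoresOnlyModel(Tmat)
    ov <- scoresOverview(m)
    expect_true(all(ov >= 0))
    for (s in 1:6) for (k in 1:5) {
        expect_equal(componentGap(m, s, k), bruteGap(Tmat, s, k))
        expect_equal(as.numeric(ov[s, k]), bruteGap(Tmat, s, k))
    }
    ## two strains: the gap is symmetric
    m2 <- scoresOnlyModel(cbind(c(1, 4), c(0, 0)))
    expect_equal(componentGap(m2, 1, 1), componentGap(m2, 2, 1))
})

test_that("bestPlane picks the two largest-gap components", {
    ## gaps on PCs 1..4 engineered as 0.1, 5.0, 0.2, 4.0 for strain 1
    Tmat <- cbind(c(0.1, 0, 0.3), c(5, 0, 10), c(0.2, 0, 0.5),
                  c(4, 0, 8))
    m <- scoresOnlyModel(Tmat)
    sel <- bestPlane(m, 1)
    expect_equal(selectedPlane(sel), c(2L, 4L))
    expect_equal(sel@gaps, c(5, 4))
    expect_equal(planeGaps(sel), c(0.1, 5, 0.2, 4))
})

test_that("identical strains tie-break to plane (PC1, PC2)", {
    Tmat <- matrix(0, 4, 3)
    m <- scoresOnlyModel(Tmat)
    sel <- bestPlane(m, 1)
    expect_equal(selectedPlane(sel), c(1L, 2L))
})

test_that("top-2 selection equals exhaustive plane search on random models", {
    set.seed(77)
    for (rep in 1:25) {
        x <- paretoScale(matrix(rlnorm(10 * 50, 10, 1), 10, 50))
        model <- fitPCA(x)
        for (s in c(1, 5, 10)) {
            top2 <- bestPlane(model, s, method = "top2")
            exh <- bestPlane(model, s, method = "exhaustive")
            expect_equal(selectedPlane(top2), selectedPlane(exh))
            expect_equal(selectedPlane(exh),
                         brutePlane(planeGaps(top2)))
        }
    }
})

test_that("plane selection is invariant to strain order", {
    sim <- generateBucketTable(synthSpec(nStrains = 6, nBackground = 60,
                                         nUniquePerStrain = 3, seed = 19))
    bt <- sim$table
    perm <- bt[, c(4, 2, 6, 1, 3, 5)]
    m1 <- fitPCA(paretoScale(normalizeSum(bt)))
    m2 <- fitPCA(paretoScale(normalizeSum(perm)))
    for (s in strainIds(bt))
        expect_equal(selectedPlane(bestPlane(m1, s)),
                     selectedPlane(bestPlane(m2, s)), info = s)
})

test_that("a strain with planted features in a shared-variance background
           selects a plane beyond the dominant components", {
    ## two groups of strains each share a large correlated block that
    ## soaks up PC1 and PC2; strain 1 sits inside group A, so in the
    ## dominant planes it is hidden in its group's crowd and its unique
    ## chemistry must surface in a higher plane
    set.seed(55)
    n <- 10; pBg <- 200
    base <- rlnorm(pBg, 10, 1)
    m <- matrix(rep(base, each = n), n, pBg) *
        matrix(rlnorm(n * pBg, 0, 0.05), n, pBg)
    blockA <- matrix(0, n, 60)
    blockA[1:6, ] <- rep(rlnorm(60, 12, 0.5), each = 6) *
        matrix(rlnorm(6 * 60, 0, 0.3), 6, 60)
    blockB <- matrix(0, n, 60)
    blockB[7:10, ] <- rep(rlnorm(60, 12, 0.5), each = 4) *
        matrix(rlnorm(4 * 60, 0, 0.3), 4, 60)
    uniq <- matrix(0, n, 2)
    uniq[1, ] <- rlnorm(2, 11, 0.5)
    raw <- cbind(m, blockA, blockB, uniq)
    rownames(raw) <- paste0("s", 1:n)
    p <- ncol(raw)
    bt <- BucketTable(raw, rt = runif(p, 2, 14),
                      mz = sort(runif(p, 150, 1500)))
    model <- fitPCA(paretoScale(normalizeSum(bt)))
    ## the two block directions dominate the model ...
    ev <- explainedVariance(model)
    expect_gt(sum(ev[1:2]) / sum(ev), 0.5)
    ## ... and strain 1 stands out only beyond them
    sel <- bestPlane(model, "s1")
    expect_true(all(selectedPlane(sel) > 2))
})

test_that("abs_deviation_from_median metric is available and non-negative", {
    set.seed(3)
    m <- scoresOnlyModel(matrix(rnorm(10), 5, 2))
    g <- scoresOverview(m, metric = "abs_deviation_from_median")
    expect_true(all(g >= 0))
    expect_equal(componentGap(m, 1, 1, "abs_deviation_from_median"),
                 abs(m@scores[1, 1] - median(m@scores[-1, 1])))
})
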
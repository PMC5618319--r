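test_that("findUnique demands exclusive presence at alpha = 0", {
    bt <- tinyTable()
    expect_equal(findUnique(bt, "A"), 2L)
    expect_equal(findUnique(bt, "B"), 3L)
    expect_equal(findUnique(bt, "C"), integer(0))
})

test_that("alpha tolerates proportionally small leakage", {
    m <- rbind(A = c(100, 100), B = c(1, 0), C = c(0, 0))
    bt <- BucketTable(m, rt = c(3, 4), mz = c(200, 300))
    expect_equal(findUnique(bt, "A", uniquenessParams(alpha = 0)), 2L)
    expect_equal(findUnique(bt, "A", uniquenessParams(alpha = 0.05)),
                 c(1L, 2L))
    ## all-zero column is unique to nobody
    m2 <- rbind(A = c(0, 5), B = c(0, 0), C = c(0, 1))
    bt2 <- BucketTable(m2, rt = c(3, 4), mz = c(200, 300))
    expect_equal(findUnique(bt2, "B"), integer(0))
})

test_that("unique sets grow monotonically in alpha", {
    set.seed(13)
    m <- matrix(rlnorm(5 * 40, 8, 2), 5, 40,
                dimnames = list(paste0("s", 1:5), NULL))
    m[m < quantile(m, 0.5)] <- 0
    bt <- BucketTable(m, rt = runif(40, 2, 14), mz = runif(40, 150, 1500))
    for (s in 1:5) {
        prev <- integer(0)
        for (a in c(0, 0.01, 0.1, 0.5)) {
            cur <- findUnique(bt, s, uniquenessParams(alpha = a))
            expect_true(all(prev %in% cur))
            prev <- cur
        }
    }
})

test_that("rankUnique sorts by descending plane distance and truncates", {
    sim <- generateBucketTable(synthSpec(nStrains = 5, nBackground = 30,
                                         nUniquePerStrain = 4, seed = 21))
    work <- normalizeSum(sim$table)
    model <- fitPCA(paretoScale(work))
    sel <- bestPlane(model, "strain_02")
    uset <- findUnique(work, "strain_02")
    rep <- rankUnique(model, sel, uset, sim$table,
                      uniquenessParams(topN = 2))
    rec <- reportRecords(rep)
    expect_equal(nrow(rec), 2L)
    d <- loadingDistance(model, selectedPlane(sel))
    expect_equal(rec$distance,
                 unname(sort(d[uset], decreasing = TRUE)[1:2]))
    expect_equal(rec$rank, 1:2)
    ## topN larger than the set returns everything
    all <- reportRecords(rankUnique(model, sel, uset, sim$table,
                                    uniquenessParams(topN = 100)))
    expect_equal(nrow(all), length(uset))
    ## ordering equals a full-sort oracle (ties toward lower index)
    expect_equal(order(-d[uset], uset)[1:2],
                 match(paste(rec$rt, rec$mz),
                       paste(featureKeys(sim$table)$rt[uset],
                             featureKeys(sim$table)$mz[uset])))
    ## empty set gives a valid empty report
    e <- rankUnique(model, sel, integer(0), sim$table)
    expect_equal(nrow(reportRecords(e)), 0L)
})

test_that("runPopcar recovers planted features with no false positives", {
    sim <- generateBucketTable(synthSpec(nStrains = 8, nBackground = 200,
                                         nUniquePerStrain = 5, seed = 37))
    reports <- runPopcar(sim$table)
    for (s in names(sim$truth)) {
        rec <- reportRecords(reports[[s]])
        expect_equal(sort(keyStrings(rec)),
                     sort(keyStrings(sim$truth[[s]])), info = s)
    }
    ## planted features of other strains never leak into a report
    for (s in names(sim$truth)) {
        others <- unlist(lapply(sim$truth[setdiff(names(sim$truth), s)],
                                keyStrings))
        expect_length(intersect(keyStrings(reportRecords(reports[[s]])),
                                others), 0)
    }
})

test_that("every reported feature re-passes the uniqueness predicate", {
    sim <- generateBucketTable(synthSpec(nStrains = 6, nBackground = 80,
                                         nUniquePerStrain = 3, seed = 57))
    reports <- runPopcar(sim$table)
    filt <- filterRanges(sim$table)
    for (s in names(reports)) {
        rec <- reportRecords(reports[[s]])
        uset <- findUnique(filt, s)
        expect_true(all(keyStrings(rec) %in%
                        keyStrings(featureKeys(filt)[uset, ])))
    }
})

test_that("identical strains yield empty reports everywhere", {
    m <- matrix(rep(c(5, 3, 8, 1), each = 4), 4, 4,
                dimnames = list(paste0("s", 1:4), NULL))
    bt <- BucketTable(m, rt = c(3, 5, 7, 9), mz = c(200, 300, 400, 500))
    reports <- runPopcar(bt)
    for (rep in reports) expect_equal(nrow(reportRecords(rep)), 0L)
})

test_that("unique sets are invariant to the surrounding group", {
    sim <- generateBucketTable(synthSpec(nStrains = 20, nBackground = 300,
                                         nUniquePerStrain = 5, seed = 61))
    big <- runPopcar(sim$table)
    small <- runPopcar(sim$table[, 1:10])
    for (s in sprintf("strain_%02d", 1:10))
        expect_equal(sort(keyStrings(reportRecords(big[[s]]))),
                     sort(keyStrings(reportRecords(small[[s]]))),
                     info = s)
})

test_that("replicate averaging integrates into the pipeline", {
    sim <- generateBucketTable(synthSpec(nStrains = 5, nBackground = 60,
                                         nUniquePerStrain = 3,
                                         nReplicates = 3, noiseCv = 0.05,
                                         seed = 71))
    expect_equal(ncol(sim$table), 15L)
    reports <- runPopcar(sim$table, replicateMap = sim$replicateMap)
    expect_equal(names(reports), sprintf("strain_%02d", 1:5))
    for (s in names(sim$truth))
        expect_equal(sort(keyStrings(reportRecords(reports[[s]]))),
                     sort(keyStrings(sim$truth[[s]])), info = s)
})

test_that("sharedFeatures lists small-group buckets excluded from reports", {
    bt <- tinyTable()
    sh <- sharedFeatures(bt, 2, 3)
    ## bucket 4 (B, C) and bucket 1 (all three strains)
    expect_equal(sort(sh$mz), c(301.1, 800.8))
    expect_equal(sh$n_strains[sh$mz == 800.8], 2)
    expect_equal(sh$strains[sh$mz == 800.8], "B;C")
})

test_that("fewer than 3 strains is refused", {
    m <- rbind(A = c(1, 2), B = c(2, 1))
    bt <- BucketTable(m, rt = c(3, 4), mz = c(200, 300))
    expect_error(runPopcar(bt), "at least 3 strains")
})
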
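test_that("neutral mass arithmetic follows M = mz*z - shift", {
    mh <- adductRule("[M+H]+", 1.007276)
    expect_equal(neutralMass(901.4205, mh), 900.413224, tolerance = 1e-9)
    expect_error(neutralMass(1.007276, mh), "non-positive")
    na <- adductRule("[M+Na]+", 22.989218)
    expect_equal(neutralMass(ionMz(100.0000, na), na), 100.0000,
                 tolerance = 1e-12)
    m2h <- adductRule("[M+2H]2+", 2 * 1.007276, 2L)
    expect_equal(neutralMass(ionMz(900, m2h), m2h), 900,
                 tolerance = 1e-12)
})

test_that("round-trip ion arithmetic is exact for every known adduct", {
    set.seed(3)
    masses <- runif(50, 100, 1400)
    for (ad in knownAdducts())
        expect_lt(max(abs(neutralMass(ionMz(masses, ad), ad) - masses)),
                  1e-9)
})

test_that("known worked case matches at ~0 ppm; distant decoy misses at 4", {
    db <- compoundDB(name = c("target", "decoy"),
                     mass = c(900.413224, 900.4200))
    res <- matchMass(901.4205, db, tolPpm = 4)
    expect_false(res$novel)
    expect_equal(res$matches$name[1], "target")
    expect_lt(abs(res$matches$ppm_error[1]), 1e-6)
    ## decoy is (900.42 - 900.413224)/900.42 * 1e6 = 7.5 ppm off: no hit
    expect_false("decoy" %in% res$matches$name)
    res10 <- matchMass(901.4205, db, tolPpm = 10)
    expect_true("decoy" %in% res10$matches$name)
})

test_that("empty database flags everything novel with a single warning", {
    db <- compoundDB(name = character(0), mass = numeric(0))
    warnState <- getFromNamespace(".emptyDBWarned", "popcar")
    if (!is.null(warnState$done)) rm("done", envir = warnState)
    expect_warning(res <- matchMass(500, db), "empty")
    expect_true(res$novel)
    expect_silent(res2 <- matchMass(600, db))
    expect_true(res2$novel)
})

test_that("binary-search matching equals a linear scan across tolerances", {
    db <- randomDB(10000, 101)
    adducts <- knownAdducts()
    set.seed(102)
    queries <- c(runif(150, 100, 1500),
                 ionMz(sample(dbEntries(db)$mass, 50), adducts[[1]]))
    for (tol in c(1, 4, 5, 10)) {
        for (q in queries) {
            got <- matchMass(q, db, adducts, tol)
            oracle <- linearScanMatch(q, db, adducts, tol)
            expect_equal(got$matches$name, oracle$name)
            expect_equal(got$matches$ppm_error, oracle$ppm_error,
                         tolerance = 1e-12)
            expect_equal(got$novel, nrow(oracle) == 0)
        }
    }
})

test_that("match sets grow monotonically with tolerance", {
    db <- randomDB(2000, 103)
    set.seed(104)
    queries <- runif(50, 100, 1500)
    for (q in queries) {
        prev <- character(0)
        for (tol in c(1, 4, 5, 10, 50)) {
            cur <- matchMass(q, db, tolPpm = tol)$matches$name
            expect_true(all(prev %in% cur))
            prev <- cur
        }
    }
})

test_that("db entries round-trip through their own ion m/z at ~0 ppm", {
    db <- randomDB(500, 105)
    e <- dbEntries(db)
    for (ad in knownAdducts()) {
        idx <- sample(nrow(e), 20)
        for (i in idx) {
            res <- matchMass(ionMz(e$mass[i], ad), db, list(ad),
                             tolPpm = 0.001)
            expect_true(e$name[i] %in% res$matches$name)
            expect_lt(abs(res$matches$ppm_error[1]), 1e-6)
        }
    }
})

test_that("annotateReport adds best matches and novelty flags in order", {
    sim <- generateBucketTable(synthSpec(nStrains = 4, nBackground = 40,
                                         nUniquePerStrain = 3, seed = 111))
    reports <- runPopcar(sim$table)
    rec <- reportRecords(reports[[1]])
    ## db contains the neutral mass of the first reported ion only
    db <- compoundDB(name = "known_one",
                     mass = rec$mz[1] - 1.007276)
    ann <- reportRecords(annotateReport(reports[[1]], db))
    expect_equal(ann$rt, rec$rt)          # order unchanged
    expect_equal(ann$match_name[1], "known_one")
    expect_false(ann$novel_flag[1])
    expect_true(all(ann$novel_flag[-1]))
    expect_true(all(is.na(ann$match_name[-1])))
    ## a fragment mass absent from the db stays flagged novel
    frag <- compoundDB(name = "x", mass = 1400.0)
    annF <- reportRecords(annotateReport(reports[[1]], frag))
    expect_true(all(annF$novel_flag))
    ## empty report passes through unchanged
    empty <- new("StrainReport", strainId = "e", plane = c(1L, 2L),
                 records = rec[0, seq_len(7)])
    expect_equal(nrow(reportRecords(annotateReport(empty, db))), 0L)
})

test_that("compound DB reads the neutral CSV schema", {
    tf <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("name,monoisotopic_mass,formula",
                 "forazoline_like,900.413224,C41H65N7O12S2",
                 "small,250.1,C10H10"), tf)
    db <- readCompoundDB(tf)
    e <- dbEntries(db)
    expect_equal(e$mass, c(250.1, 900.413224))   # sorted ascending
    expect_equal(e$name[2], "forazoline_like")
    expect_error(readCompoundDB(textConnection("x,y\n1,2")))
})
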
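## small hand-built bucket table: 3 strains x 4 buckets
## bucket 1 shared, bucket 2 unique to A, bucket 3 unique to B,
## bucket 4 shared by B and C
tinyTable <- function() {
    m <- rbind(A = c(100, 50, 0, 0),
               B = c(200, 0, 30, 10),
               C = c(150, 0, 0, 20))
    BucketTable(m, rt = c(3.0, 5.5, 9.65, 12.0),
                mz = c(301.1, 450.2, 1185.7445, 800.8))
}

## random centered matrix for PCA properties
randomScaled <- function(n, p, seed) {
    set.seed(seed)
    paretoScale(matrix(rlnorm(n * p, 10, 1), n, p))
}

## random compound database of n entries in [100, 1500] Da
randomDB <- function(n, seed) {
    set.seed(seed)
    compoundDB(name = sprintf("cmpd_%05d", seq_len(n)),
               mass = sort(runif(n, 100, 1500)))
}

## brute-force linear-scan mass matcher (oracle for matchMass)
linearScanMatch <- function(mz, db, adducts, tolPpm) {
    e <- dbEntries(db)
    hits <- list()
    for (ad in adducts) {
        M <- mz * ad$charge - ad$massShift
        if (M <= 0) next
        ppm <- (M - e$mass) / e$mass * 1e6
        keep <- which(abs(ppm) <= tolPpm)
        if (length(keep))
            hits[[length(hits) + 1L]] <-
                data.frame(name = e$name[keep], adduct = ad$label,
                           ppm_error = ppm[keep], mass = e$mass[keep])
    }
    out <- if (length(hits)) do.call(rbind, hits)
           else data.frame(name = character(), adduct = character(),
                           ppm_error = numeric(), mass = numeric())
    out <- out[order(abs(out$ppm_error)), , drop = FALSE]
    rownames(out) <- NULL
    out
}

## brute-force per-strain, per-component nearest-neighbor gap (oracle)
bruteGap <- function(scores, s, k) {
    best <- Inf
    for (r in seq_len(nrow(scores)))
        if (r != s) best <- min(best, abs(scores[s, k] - scores[r, k]))
    best
}

## exhaustive plane search oracle: maximize min(gap_i, gap_j) over all
## pairs, ties by max gap then lower indices; returns oriented pair
brutePlane <- function(gaps) {
    K <- length(gaps)
    best <- NULL
    bestKey <- c(-Inf, -Inf)
    for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
        key <- c(min(gaps[i], gaps[j]), max(gaps[i], gaps[j]))
        if (key[1] > bestKey[1] + 1e-15 ||
            (abs(key[1] - bestKey[1]) <= 1e-15 &&
             key[2] > bestKey[2] + 1e-15)) {
            bestKey <- key
            best <- c(i, j)
        }
    }
    if (gaps[best[2]] > gaps[best[1]]) rev(best) else best
}

## (rt, mz) keys as comparable strings
keyStrings <- function(df) sprintf("%.6f_%.8f", df$rt, df$mz)
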
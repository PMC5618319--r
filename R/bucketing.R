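#' Bucketing tolerance parameters
#'
#' Defaults follow common practice for high-resolution Q-TOF data:
#' retention-time window 0.33 min and mass window 4 ppm.
#'
#' @param deltaRt retention-time tolerance in minutes (> 0).
#' @param deltaPpm mass tolerance in ppm (> 0).
#' @return validated parameter list.
#' @export
bucketingParams <- function(deltaRt = 0.33, deltaPpm = 4) {
    stopifnot(deltaRt > 0, deltaPpm > 0)
    list(deltaRt = deltaRt, deltaPpm = deltaPpm)
}

#' Merge per-sample feature lists into a bucket table
#'
#' Groups (rt, m/z, intensity) features from several samples into shared
#' buckets. All features from all samples are pooled and sorted by m/z
#' (ties: rt, then sample id), then swept once: each feature joins the
#' nearest-in-ppm existing bucket whose intensity-weighted centroid lies
#' within both tolerances (ppm ties break toward the lower-m/z centroid),
#' or opens a new bucket. Centroids are intensity-weighted means of their
#' members; same-sample collisions within one bucket are summed so total
#' signal is conserved. The sort makes the result invariant to the order
#' of samples and of features within a sample.
#'
#' @param samples named list of per-sample feature data.frames with
#'   columns \code{rt}, \code{mz}, \code{intensity}; names are sample ids.
#'   Alternatively a single long data.frame with a \code{sample} column.
#' @param params a [bucketingParams()] list.
#' @return a \linkS4class{BucketTable} with one row per sample and one
#'   column per bucket, buckets ordered by (rt, mz).
#' @examples
#' s <- data.frame(rt = c(5.0, 5.1), mz = c(500.0000, 500.0010),
#'                 intensity = c(10, 20))
#' bucketFeatures(list(a = s, b = s))   # 2.0 ppm apart -> one bucket
#' @export
bucketFeatures <- function(samples, params = bucketingParams()) {
    if (is.data.frame(samples)) {
        stopifnot("sample" %in% colnames(samples))
        samples <- split(samples[c("rt", "mz", "intensity")],
                         samples$sample)
    }
    stopifnot(length(samples) >= 1)
    if (is.null(names(samples)) || any(!nzchar(names(samples))))
        stop("samples must be named by sample id")
    pooled <- do.call(rbind, lapply(names(samples), function(s) {
        f <- samples[[s]]
        if (!nrow(f))
            return(data.frame(sample = character(), rt = numeric(),
                              mz = numeric(), intensity = numeric()))
        stopifnot(all(c("rt", "mz", "intensity") %in% colnames(f)))
        if (any(f$intensity < 0))
            stop("negative intensity in sample '", s, "'")
        data.frame(sample = s, rt = f$rt, mz = f$mz,
                   intensity = f$intensity)
    }))
    sampleIds <- names(samples)
    if (!nrow(pooled)) {
        m <- matrix(0, nrow = length(sampleIds), ncol = 0,
                    dimnames = list(sampleIds, NULL))
        return(BucketTable(m, rt = numeric(), mz = numeric(),
                           meta = list(history = "bucket_features")))
    }
    ord <- order(pooled$mz, pooled$rt, pooled$sample)
    pooled <- pooled[ord, , drop = FALSE]
    n <- nrow(pooled)
    ## open buckets tracked as running weighted sums; the m/z sort means a
    ## bucket can be closed once the sweep passes beyond its ppm window
    capacity <- n
    cRt <- cSum <- cMz <- cW <- numeric(capacity)   # weighted sums / totals
    assign <- integer(n)
    nb <- 0L
    active <- integer(0)
    tolPpm <- params$deltaPpm * 1e-6
    for (i in seq_len(n)) {
        mzi <- pooled$mz[i]; rti <- pooled$rt[i]; wi <- pooled$intensity[i]
        ## retire buckets whose centroid can no longer match (sorted m/z)
        if (length(active)) {
            cen <- cMz[active] / pmax(cW[active], .Machine$double.xmin)
            keep <- (mzi - cen) / ((mzi + cen) / 2) <= tolPpm
            active <- active[keep]
        }
        best <- 0L; bestPpm <- Inf; bestMz <- Inf
        for (b in active) {
            w <- cW[b]
            cenMz <- if (w > 0) cMz[b] / w else cSum[b]
            cenRt <- if (w > 0) cRt[b] / w else 0
            dppm <- abs(mzi - cenMz) / ((mzi + cenMz) / 2)
            if (dppm <= tolPpm && abs(rti - cenRt) <= params$deltaRt) {
                if (dppm < bestPpm - 1e-15 ||
                    (abs(dppm - bestPpm) <= 1e-15 && cenMz < bestMz)) {
                    best <- b; bestPpm <- dppm; bestMz <- cenMz
                }
            }
        }
        if (best == 0L) {
            nb <- nb + 1L
            best <- nb
            active <- c(active, nb)
        }
        assign[i] <- best
        cW[best] <- cW[best] + wi
        cMz[best] <- cMz[best] + wi * mzi
        cRt[best] <- cRt[best] + wi * rti
        cSum[best] <- mzi   # fallback centroid for zero-intensity buckets
    }
    ## centroids; zero-weight buckets fall back to plain means
    cenMz <- cenRt <- numeric(nb)
    for (b in seq_len(nb)) {
        sel <- assign == b
        if (cW[b] > 0) {
            cenMz[b] <- cMz[b] / cW[b]
            cenRt[b] <- cRt[b] / cW[b]
        } else {
            cenMz[b] <- mean(pooled$mz[sel])
            cenRt[b] <- mean(pooled$rt[sel])
        }
    }
    ## cell values: per-sample sums; canonical bucket order by (rt, mz)
    m <- matrix(0, nrow = length(sampleIds), ncol = nb,
                dimnames = list(sampleIds, NULL))
    idx <- cbind(match(pooled$sample, sampleIds), assign)
    for (k in seq_len(n))
        m[idx[k, 1], idx[k, 2]] <- m[idx[k, 1], idx[k, 2]] +
            pooled$intensity[k]
    bord <- order(cenRt, cenMz)
    BucketTable(m[, bord, drop = FALSE], rt = cenRt[bord], mz = cenMz[bord],
                meta = list(history = "bucket_features",
                            params = params))
}

#' Average replicate rows into strain rows
#'
#' Collapses replicate analyses to one row per strain by the feature-wise
#' arithmetic mean. Averaging replicates after feature finding keeps the
#' PCA model small while preserving per-strain intensity structure; it is
#' applied before normalization and scaling.
#'
#' @param table a \linkS4class{BucketTable} whose rows are replicates.
#' @param groups named character vector or list mapping every replicate id
#'   (names) to its strain id (values).
#' @return a \linkS4class{BucketTable} with one row per strain, strains in
#'   first-appearance order of the mapping over the table's rows.
#' @export
averageReplicates <- function(table, groups) {
    groups <- unlist(groups)
    reps <- strainIds(table)
    missing <- setdiff(reps, names(groups))
    if (length(missing))
        stop("replicate ids without a strain mapping: ",
             paste(missing, collapse = ", "))
    g <- as.character(groups[reps])
    strains <- unique(g)
    m <- intensityMatrix(table)
    out <- matrix(0, nrow = length(strains), ncol = ncol(m),
                  dimnames = list(strains, colnames(m)))
    for (s in strains) {
        sel <- g == s
        out[s, ] <- colMeans(m[sel, , drop = FALSE])
    }
    keys <- featureKeys(table)
    bt <- BucketTable(out, rt = keys$rt, mz = keys$mz,
                      meta = S4Vectors::metadata(table))
    .tagHistory(bt, "average_replicates")
}
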
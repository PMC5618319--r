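#' Specification for a synthetic strain-collection bucket table
#'
#' Describes a simulated LC-MS profiling experiment over a collection of
#' bacterial strains: a large set of background buckets shared by all
#' strains (media components, common primary metabolites), a small set of
#' strain-exclusive buckets per strain (the planted "unique chemistry"),
#' log-normal intensities (the heavy right tail typical of LC-MS), a
#' per-strain global intensity factor (culture density / ionization
#' disparities between strains), optional per-strain dropout of
#' background buckets, and optional replicates with multiplicative
#' log-normal noise (constant-CV detector behavior).
#'
#' @param nStrains number of strains.
#' @param nBackground number of shared background buckets.
#' @param nUniquePerStrain exclusive buckets planted per strain.
#' @param intensityMeanlog,intensitySdlog log-normal parameters of bucket
#'   intensities (defaults give a median of ~4e5 counts with a spread of
#'   about one order of magnitude).
#' @param strainFactorRange range of the per-strain intensity multiplier
#'   (default 0.25-1, a ~4-fold disparity between the weakest- and
#'   strongest-ionizing strains).
#' @param dropoutRate probability a background bucket is missing from a
#'   given strain.
#' @param nReplicates replicate analyses per strain.
#' @param noiseCv coefficient of variation of the multiplicative
#'   replicate noise.
#' @param rtRange,mzRange ranges the bucket keys are drawn from
#'   (defaults sit inside the standard 2-14 min / m/z 150-1500 windows).
#' @param minSepPpm minimum mutual m/z separation of generated keys
#'   (default 20 ppm) so that 4-ppm bucketing ground truth is
#'   unambiguous.
#' @param seed integer; fixes the full output.
#' @return validated specification list.
#' @export
synthSpec <- function(nStrains = 20, nBackground = 2000,
                      nUniquePerStrain = 5,
                      intensityMeanlog = log(4e5), intensitySdlog = 1,
                      strainFactorRange = c(0.25, 1),
                      dropoutRate = 0, nReplicates = 1, noiseCv = 0.05,
                      rtRange = c(2, 14), mzRange = c(150, 1500),
                      minSepPpm = 20, seed = 1L) {
    stopifnot(nStrains >= 1, nBackground >= 0, nUniquePerStrain >= 0,
              dropoutRate >= 0, dropoutRate <= 1, nReplicates >= 1,
              noiseCv >= 0, length(strainFactorRange) == 2,
              all(strainFactorRange > 0), seed == as.integer(seed))
    list(nStrains = nStrains, nBackground = nBackground,
         nUniquePerStrain = nUniquePerStrain,
         intensityMeanlog = intensityMeanlog,
         intensitySdlog = intensitySdlog,
         strainFactorRange = strainFactorRange,
         dropoutRate = dropoutRate, nReplicates = nReplicates,
         noiseCv = noiseCv, rtRange = rtRange, mzRange = mzRange,
         minSepPpm = minSepPpm, seed = as.integer(seed))
}

## draw n (rt, mz) keys with pairwise m/z separation >= minSepPpm;
## offending draws are replaced, up to 100 rounds
.drawKeys <- function(n, spec) {
    if (n == 0) return(data.frame(rt = numeric(), mz = numeric()))
    rt <- stats::runif(n, spec$rtRange[1], spec$rtRange[2])
    mz <- stats::runif(n, spec$mzRange[1], spec$mzRange[2])
    for (iter in seq_len(100)) {
        o <- order(mz)
        sep <- diff(mz[o]) / mz[o][-n] * 1e6
        bad <- o[-1][sep < spec$minSepPpm]
        if (!length(bad)) return(data.frame(rt = rt, mz = mz))
        mz[bad] <- stats::runif(length(bad), spec$mzRange[1],
                                spec$mzRange[2])
    }
    stop("could not draw ", n, " mutually separated m/z keys ",
         "after 100 redraws")
}

## multiplicative log-normal noise with unit mean and the given CV
.cvNoise <- function(n, cv) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Generate a synthetic bucket table with known ground truth
#'
#' Builds the strains-by-buckets intensity table described by a
#' [synthSpec()]: shared background buckets (minus dropout), planted
#' strain-exclusive buckets, per-strain intensity factors, and optional
#' replicates with multiplicative noise. Noise is between-replicate
#' (injection/detector) variation, so it enters only when
#' \code{nReplicates > 1}; a single analysis per strain is that strain's
#' clean profile. Fully reproducible from the spec's seed.
#'
#' @param spec a [synthSpec()].
#' @return list with elements \code{table}
#'   (\linkS4class{BucketTable}; rows are replicates when
#'   \code{nReplicates > 1}, otherwise strains), \code{truth} (named list:
#'   strain id -> data.frame of planted \code{rt, mz} keys),
#'   \code{replicateMap} (named vector replicate id -> strain id, NULL
#'   for single replicates) and \code{backgroundKeys}.
#' @examples
#' sim <- generateBucketTable(synthSpec(nStrains = 3, nBackground = 10,
#'                                      nUniquePerStrain = 2, seed = 1))
#' sim$table
#' sim$truth
#' @export
generateBucketTable <- function(spec = synthSpec()) {
    set.seed(spec$seed)
    nS <- spec$nStrains
    nB <- spec$nBackground
    nU <- spec$nUniquePerStrain
    strains <- sprintf("strain_%02d", seq_len(nS))
    keys <- .drawKeys(nB + nS * nU, spec)
    bg <- keys[seq_len(nB), , drop = FALSE]
    uq <- keys[-seq_len(nB), , drop = FALSE]
    truth <- lapply(seq_len(nS), function(s) {
        if (nU == 0) return(data.frame(rt = numeric(), mz = numeric()))
        idx <- ((s - 1) * nU + 1):(s * nU)
        data.frame(rt = uq$rt[idx], mz = uq$mz[idx])
    })
    names(truth) <- strains
    factor <- stats::runif(nS, spec$strainFactorRange[1],
                           spec$strainFactorRange[2])
    ## strain-level table: background (shared base intensity x strain
    ## factor, with dropout) then planted unique blocks
    base <- stats::rlnorm(nB, spec$intensityMeanlog, spec$intensitySdlog)
    m <- matrix(0, nrow = nS, ncol = nB + nS * nU,
                dimnames = list(strains, NULL))
    if (nB > 0)
        for (s in seq_len(nS)) {
            keep <- stats::runif(nB) >= spec$dropoutRate
            m[s, seq_len(nB)] <- base * factor[s] * keep
        }
    if (nU > 0)
        for (s in seq_len(nS)) {
            idx <- nB + ((s - 1) * nU + 1):(s * nU)
            m[s, idx] <- stats::rlnorm(nU, spec$intensityMeanlog,
                                       spec$intensitySdlog) * factor[s]
        }
    allKeys <- rbind(bg, uq)
    ord <- order(allKeys$rt, allKeys$mz)
    m <- m[, ord, drop = FALSE]
    allKeys <- allKeys[ord, , drop = FALSE]
    replicateMap <- NULL
    if (spec$nReplicates > 1) {
        reps <- as.vector(t(outer(strains, seq_len(spec$nReplicates),
                                  function(s, r) sprintf("%s_r%d", s, r))))
        replicateMap <- stats::setNames(rep(strains,
                                            each = spec$nReplicates), reps)
        mm <- matrix(0, nrow = length(reps), ncol = ncol(m),
                     dimnames = list(reps, NULL))
        for (i in seq_along(reps)) {
            s <- match(replicateMap[i], strains)
            mm[i, ] <- m[s, ] * .cvNoise(ncol(m), spec$noiseCv)
        }
        m <- mm
    }
    table <- BucketTable(m, rt = allKeys$rt, mz = allKeys$mz,
                         meta = list(history = "synthetic",
                                     seed = spec$seed))
    list(table = table, truth = truth, replicateMap = replicateMap,
         backgroundKeys = bg)
}

#' Generate jittered per-sample feature lists
#'
#' Emits per-sample (rt, mz, intensity) lists in which every true bucket
#' appears once per sample with small random retention-time and mass
#' jitter — the shape of feature-finding output before bucketing. With
#' jitter well below half the bucketing tolerances, [bucketFeatures()] at
#' default parameters reconstructs exactly the true bucket count.
#'
#' @param spec a [synthSpec()]; \code{nStrains} plays the role of the
#'   sample count and only background (shared) buckets are emitted.
#' @param jitterPpm mass jitter half-width in ppm (uniform).
#' @param jitterRt retention-time jitter half-width in minutes (uniform).
#' @return list with \code{samples} (named list of per-sample
#'   data.frames) and \code{truth} (data.frame of true \code{rt, mz}
#'   keys).
#' @export
generateFeatureLists <- function(spec = synthSpec(), jitterPpm = 1,
                                 jitterRt = 0.05) {
    set.seed(spec$seed)
    keys <- .drawKeys(spec$nBackground, spec)
    samples <- lapply(seq_len(spec$nStrains), function(s) {
        n <- nrow(keys)
        data.frame(
            rt = keys$rt + stats::runif(n, -jitterRt, jitterRt),
            mz = keys$mz * (1 + stats::runif(n, -jitterPpm, jitterPpm)
                            * 1e-6),
            intensity = stats::rlnorm(n, spec$intensityMeanlog,
                                      spec$intensitySdlog))
    })
    names(samples) <- sprintf("sample_%02d", seq_len(spec$nStrains))
    list(samples = samples, truth = keys)
}
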
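#' Preprocessing parameters
#'
#' Defaults match routine untargeted profiling on a 14-min reversed-phase
#' gradient: retention time restricted to 2-14 min (cuts injection front
#' and column wash) and m/z to 150-1500 (cuts solvent/background ions and
#' poorly calibrated high masses).
#'
#' @param rtMin,rtMax retention-time window in minutes.
#' @param mzMin,mzMax mass window in Th.
#' @param normalize logical; divide each strain row by its total
#'   intensity.
#' @param scale \code{"pareto"} or \code{"none"}.
#' @return validated parameter list.
#' @export
preprocessParams <- function(rtMin = 2, rtMax = 14, mzMin = 150,
                             mzMax = 1500, normalize = TRUE,
                             scale = c("pareto", "none")) {
    stopifnot(rtMin < rtMax, mzMin < mzMax)
    list(rtMin = rtMin, rtMax = rtMax, mzMin = mzMin, mzMax = mzMax,
         normalize = isTRUE(normalize), scale = match.arg(scale))
}

#' Filter buckets by retention-time and mass range
#'
#' Keeps buckets with \code{rtMin <= rt <= rtMax} and
#' \code{mzMin <= mz <= mzMax} (closed intervals). Strains unchanged.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param params a [preprocessParams()] list.
#' @return the filtered \linkS4class{BucketTable}.
#' @export
filterRanges <- function(table, params = preprocessParams()) {
    keys <- featureKeys(table)
    keep <- keys$rt >= params$rtMin & keys$rt <= params$rtMax &
            keys$mz >= params$mzMin & keys$mz <= params$mzMax
    .tagHistory(table[keep, ], "filter_ranges")
}

#' Sum-normalize strain rows
#'
#' Divides each strain's intensities by that strain's total so every row
#' sums to one. This corrects per-strain differences in overall ion
#' intensity (culture density, extraction yield, ionization), without
#' which low-yield strains would appear to have fewer unique features.
#'
#' @param table a \linkS4class{BucketTable}.
#' @return the normalized \linkS4class{BucketTable}.
#' @export
normalizeSum <- function(table) {
    m <- SummarizedExperiment::assay(table, "intensity")
    tot <- colSums(m)
    if (any(tot <= 0))
        stop("all-zero intensity row for strain(s): ",
             paste(colnames(m)[tot <= 0], collapse = ", "))
    SummarizedExperiment::assay(table, "intensity") <-
        sweep(m, 2, tot, "/")
    .tagHistory(table, "normalize_sum")
}

#' Pareto-scale a matrix column-wise
#'
#' Per feature column j: \eqn{x'_{ij} = (x_{ij} - \bar x_j)/\sqrt{s_j}}
#' with \eqn{s_j} the sample (n-1 denominator) standard deviation. The
#' square-root divisor down-weights intense features less aggressively
#' than unit-variance scaling, preserving some of the original intensity
#' ordering while still letting low-abundance features contribute.
#' Zero-variance columns are set to all-zero (not dropped) so feature
#' indices stay aligned with the bucket table; they contribute nothing to
#' the PCA.
#'
#' @param x a strains-by-features numeric matrix, or a
#'   \linkS4class{BucketTable} (its intensity matrix is scaled).
#' @return numeric matrix of the same shape; column means are 0 and
#'   column variances equal the original column standard deviations.
#' @export
setGeneric("paretoScale", function(x) standardGeneric("paretoScale"))

#' @rdname paretoScale
#' @export
setMethod("paretoScale", "matrix", function(x) {
    if (nrow(x) < 2)
        stop("Pareto scaling needs at least 2 rows (sd undefined)")
    mu <- colMeans(x)
    s <- apply(x, 2, stats::sd)
    out <- sweep(x, 2, mu, "-")
    pos <- s > 0
    out[, pos] <- sweep(out[, pos, drop = FALSE], 2, sqrt(s[pos]), "/")
    out[, !pos] <- 0
    out
})

#' @rdname paretoScale
#' @export
setMethod("paretoScale", "BucketTable", function(x)
    paretoScale(intensityMatrix(x)))
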
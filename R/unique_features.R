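#' Uniqueness parameters
#'
#' @param alpha maximum intensity any other strain may show in a bucket,
#'   as a fraction of the owner's intensity, for the bucket still to count
#'   as unique. The default 0 demands strictly exclusive presence; a small
#'   positive value tolerates near-zero noise buckets.
#' @param topN maximum number of ranked features reported per strain.
#' @return validated parameter list.
#' @export
uniquenessParams <- function(alpha = 0, topN = 60) {
    stopifnot(alpha >= 0, alpha < 1, topN >= 1)
    list(alpha = alpha, topN = topN)
}

#' Find features unique to one strain in the bucket table
#'
#' A bucket belongs to a strain's unique set iff the strain's intensity is
#' positive and every other strain's intensity is at most
#' \code{alpha} times the owner's. Uniqueness is decided on the bucket
#' table itself (normalized but unscaled), not on PCA output: presence or
#' absence is a property of the data, while PCA supplies the plane and
#' the ranking.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param strain strain id (character) or row index.
#' @param params a [uniquenessParams()] list.
#' @return integer vector of 1-based feature (bucket) indices.
#' @export
findUnique <- function(table, strain, params = uniquenessParams()) {
    m <- intensityMatrix(table)
    s <- if (is.character(strain)) {
        i <- match(strain, rownames(m))
        if (is.na(i)) stop("unknown strain: ", strain)
        i
    } else as.integer(strain)
    own <- m[s, ]
    others <- m[-s, , drop = FALSE]
    maxOther <- if (nrow(others)) apply(others, 2, max) else rep(0, ncol(m))
    unname(which(own > 0 & maxOther <= params$alpha * own))
}

#' Rank a strain's unique features by loading distance in its best plane
#'
#' @param model the \linkS4class{PCAModel} fitted to the same (scaled)
#'   table the unique set was computed on.
#' @param selection the strain's \linkS4class{PlaneSelection}.
#' @param uniqueSet integer feature indices from [findUnique()].
#' @param table the \linkS4class{BucketTable} supplying feature keys and
#'   the reported (raw) intensities.
#' @param params a [uniquenessParams()] list (supplies \code{topN}).
#' @param distanceSpace \code{"plane"} ranks by Euclidean distance in the
#'   selected plane (default); \code{"full"} uses all K components.
#' @return a \linkS4class{StrainReport} with at most \code{topN} records,
#'   ranked by descending distance (ties toward the lower feature index).
#' @export
rankUnique <- function(model, selection, uniqueSet, table,
                       params = uniquenessParams(),
                       distanceSpace = c("plane", "full")) {
    distanceSpace <- match.arg(distanceSpace)
    plane <- selectedPlane(selection)
    keys <- featureKeys(table)
    m <- intensityMatrix(table)
    sid <- selection@strainId
    empty <- data.frame(rank = integer(), rt = numeric(), mz = numeric(),
                        distance = numeric(), pc_i = integer(),
                        pc_j = integer(), intensity = numeric())
    if (!length(uniqueSet))
        return(methods::new("StrainReport", strainId = sid,
                            plane = plane, records = empty))
    d <- if (distanceSpace == "plane")
        loadingDistance(model, plane)
    else
        sqrt(rowSums(model@loadings^2))
    du <- d[uniqueSet]
    ord <- order(-du, uniqueSet)
    take <- utils::head(ord, params$topN)
    idx <- uniqueSet[take]
    rec <- data.frame(rank = seq_along(idx),
                      rt = keys$rt[idx], mz = keys$mz[idx],
                      distance = du[take],
                      pc_i = plane[1], pc_j = plane[2],
                      intensity = m[sid, idx])
    methods::new("StrainReport", strainId = sid, plane = plane,
                 records = rec)
}

#' Features shared by a small group of strains
#'
#' Complementary listing: buckets present in exactly \code{minStrains} to
#' \code{maxStrains} strains (and absent elsewhere) — the "small group of
#' similar strains" pattern that per-strain unique reports exclude by
#' definition.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param minStrains,maxStrains group-size window (defaults 2-3).
#' @return data.frame with columns \code{rt, mz, n_strains, strains}.
#' @export
sharedFeatures <- function(table, minStrains = 2, maxStrains = 3) {
    m <- intensityMatrix(table)
    pres <- m > 0
    n <- colSums(pres)
    sel <- which(n >= minStrains & n <= maxStrains)
    keys <- featureKeys(table)
    data.frame(rt = keys$rt[sel], mz = keys$mz[sel], n_strains = n[sel],
               strains = vapply(sel, function(j)
                   paste(rownames(m)[pres[, j]], collapse = ";"), ""),
               row.names = NULL)
}

#' Run the full PoPCAR workflow
#'
#' End-to-end pipeline: optional replicate averaging, retention-time and
#' mass range filtering, sum normalization, Pareto scaling, PCA, then per
#' strain: selection of the PC plane with the largest separation gaps,
#' extraction of the strain's unique buckets from the (filtered,
#' normalized) table, ranking by loading distance in the selected plane,
#' and optional dereplication against a compound database. Strains with
#' no unique buckets yield empty reports.
#'
#' @param table a \linkS4class{BucketTable} (rows = analyses).
#' @param replicateMap optional named vector mapping replicate ids to
#'   strain ids; if given, replicates are averaged first.
#' @param preprocess a [preprocessParams()] list.
#' @param uniq a [uniquenessParams()] list.
#' @param db optional \linkS4class{CompoundDB} for dereplication.
#' @param adducts adduct rules for dereplication, see [adductRule()].
#' @param tolPpm dereplication mass tolerance in ppm.
#' @param gapMetric see [componentGap()].
#' @param distanceSpace see [rankUnique()].
#' @param verbose log per-stage feature counts (the triage narrative:
#'   input buckets, after range filter, unique per strain).
#' @return named list of \linkS4class{StrainReport}, one per strain.
#' @examples
#' sim <- generateBucketTable(synthSpec(nStrains = 5, nBackground = 50,
#'                                      nUniquePerStrain = 2, seed = 1))
#' reports <- runPopcar(sim$table)
#' reports[[1]]
#' @export
runPopcar <- function(table, replicateMap = NULL,
                      preprocess = preprocessParams(),
                      uniq = uniquenessParams(),
                      db = NULL, adducts = defaultAdducts(), tolPpm = 5,
                      gapMetric = "nearest_neighbor",
                      distanceSpace = "plane",
                      verbose = FALSE) {
    log <- function(...) if (verbose) message(sprintf(...))
    if (!is.null(replicateMap)) {
        table <- averageReplicates(table, replicateMap)
        log("averaged %d replicates into %d strains",
            length(replicateMap), ncol(table))
    }
    if (ncol(table) < 3)
        stop("plane search needs at least 3 strains")
    log("input buckets: %d", nrow(table))
    filtered <- filterRanges(table, preprocess)
    log("after rt/mz range filter: %d", nrow(filtered))
    work <- if (preprocess$normalize) normalizeSum(filtered) else filtered
    scaled <- if (preprocess$scale == "pareto") paretoScale(work)
              else {
                  x <- intensityMatrix(work)
                  sweep(x, 2, colMeans(x), "-")
              }
    model <- fitPCA(scaled)
    log("PCA: %d components retained", pcaRank(model))
    reports <- list()
    for (s in strainIds(filtered)) {
        sel <- bestPlane(model, s, metric = gapMetric)
        uset <- findUnique(work, s, uniq)
        rep <- rankUnique(model, sel, uset, filtered, uniq,
                          distanceSpace = distanceSpace)
        if (!is.null(db))
            rep <- annotateReport(rep, db, adducts, tolPpm)
        log("strain %s: plane PC%d vs. PC%d, %d unique (reporting %d)",
            s, selectedPlane(sel)[1], selectedPlane(sel)[2],
            length(uset), nrow(reportRecords(rep)))
        reports[[s]] <- rep
    }
    reports
}
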
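#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- rowData
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom stats median quantile rlnorm runif sd setNames
#' @importFrom utils read.csv read.delim write.csv
NULL

#' BucketTable: strains-by-buckets intensity matrix
#'
#' Container for an LC-MS bucket table: non-negative intensities for a set
#' of strains (samples) over a set of retention-time / m/z buckets. Extends
#' \linkS4class{SummarizedExperiment}: rows are buckets (features) with
#' \code{rt} (minutes) and \code{mz} (Th) columns in \code{rowData}, columns
#' are strains. A zero intensity encodes absence; the table is dense.
#'
#' @slot .. inherited from \code{SummarizedExperiment}; the single assay is
#'   named \code{"intensity"}.
#' @seealso [BucketTable()], [readBucketTable()], [bucketFeatures()]
#' @export
setClass("BucketTable", contains = "SummarizedExperiment")

.validBucketTable <- function(object) {
    msg <- character()
    a <- SummarizedExperiment::assay(object, withDimnames = FALSE)
    if (anyNA(a))
        msg <- c(msg, "intensities must not contain NA (encode absence as 0)")
    else if (nrow(a) && ncol(a) && any(a < 0))
        msg <- c(msg, "intensities must be non-negative")
    rd <- SummarizedExperiment::rowData(object)
    if (!all(c("rt", "mz") %in% colnames(rd))) {
        msg <- c(msg, "rowData must contain 'rt' and 'mz'")
    } else if (nrow(rd)) {
        if (any(rd$rt <= 0) || any(rd$mz <= 0))
            msg <- c(msg, "rt and mz must be positive")
        if (anyDuplicated(paste(rd$rt, rd$mz)))
            msg <- c(msg, "duplicate (rt, mz) feature keys")
    }
    sid <- colnames(object)
    if (is.null(sid) && ncol(object) > 0)
        msg <- c(msg, "strain ids (colnames) are required")
    if (anyDuplicated(sid))
        msg <- c(msg, sprintf("duplicate strain ids: %s",
                 paste(unique(sid[duplicated(sid)]), collapse = ", ")))
    if (length(msg)) msg else TRUE
}
setValidity("BucketTable", .validBucketTable)

#' Construct a BucketTable
#'
#' @param intensity numeric matrix of non-negative intensities, strains in
#'   rows and buckets in columns (the shape vendor software exports);
#'   rownames are the strain ids.
#' @param rt,mz numeric vectors of bucket retention times (minutes) and
#'   mass-to-charge values (Th), one per column of \code{intensity}.
#' @param strainIds optional character vector overriding
#'   \code{rownames(intensity)}.
#' @param meta named list of provenance entries stored in \code{metadata()}.
#' @return a \linkS4class{BucketTable}.
#' @examples
#' m <- rbind(A = c(10, 0), B = c(0, 5))
#' bt <- BucketTable(m, rt = c(2.5, 9.65), mz = c(301.1, 1185.7445))
#' bt
#' @export
BucketTable <- function(intensity, rt, mz, strainIds = rownames(intensity),
                        meta = list()) {
    intensity <- as.matrix(intensity)
    if (length(rt) != ncol(intensity) || length(mz) != ncol(intensity))
        stop("rt/mz length must equal the number of buckets")
    if (is.null(strainIds) && nrow(intensity) > 0)
        stop("strain ids are required (rownames of 'intensity')")
    x <- t(intensity)                       # internal: features x strains
    rownames(x) <- featureIds(rt, mz)
    colnames(x) <- strainIds
    se <- SummarizedExperiment::SummarizedExperiment(
        assays  = list(intensity = x),
        rowData = S4Vectors::DataFrame(rt = as.numeric(rt),
                                       mz = as.numeric(mz)),
        metadata = meta)
    methods::new("BucketTable", se)
}

## canonical feature identifier; 6 decimals on m/z so 4-ppm distinctions at
## m/z <= 1500 survive a round-trip through text
featureIds <- function(rt, mz) {
    if (!length(rt)) return(character())
    sprintf("%.4fmin_%.6fmz", rt, mz)
}

#' @describeIn BucketTable number of strains / buckets and a preview
#' @param object a \code{BucketTable}
#' @export
setMethod("show", "BucketTable", function(object) {
    cat(sprintf("BucketTable: %d strains x %d buckets\n",
                ncol(object), nrow(object)))
    if (ncol(object))
        cat("strains:", paste(utils::head(colnames(object), 6),
            collapse = ", "),
            if (ncol(object) > 6) "..." else "", "\n")
    rd <- SummarizedExperiment::rowData(object)
    if (nrow(rd))
        cat(sprintf("rt range: %.2f-%.2f min; m/z range: %.4f-%.4f\n",
                    min(rd$rt), max(rd$rt), min(rd$mz), max(rd$mz)))
    h <- S4Vectors::metadata(object)$history
    if (!is.null(h)) cat("history:", paste(h, collapse = " -> "), "\n")
    invisible(NULL)
})

#' Accessors for BucketTable
#'
#' \code{strainIds} returns the strain labels; \code{featureKeys} the
#' (rt, mz) key table; \code{intensityMatrix} the strains-by-buckets
#' numeric matrix (the transpose of the internal assay).
#'
#' @param x a \linkS4class{BucketTable}
#' @return see individual descriptions.
#' @export
strainIds <- function(x) colnames(x)

#' @rdname strainIds
#' @export
featureKeys <- function(x) {
    rd <- SummarizedExperiment::rowData(x)
    data.frame(rt = rd$rt, mz = rd$mz, row.names = rownames(x))
}

#' @rdname strainIds
#' @export
intensityMatrix <- function(x)
    t(SummarizedExperiment::assay(x, "intensity"))

## append a processing-history tag to metadata
.tagHistory <- function(x, tag) {
    S4Vectors::metadata(x)$history <-
        c(S4Vectors::metadata(x)$history, tag)
    x
}

#' PCAModel: scores, loadings and explained variance
#'
#' Result of [fitPCA()]. Scores \eqn{T = U S} place strains in component
#' space; loadings \eqn{P} (orthonormal columns) place features; the
#' explained variance per component is \eqn{S_k^2/(n-1)}.
#'
#' @slot scores numeric matrix, strains x K.
#' @slot loadings numeric matrix, features x K, orthonormal columns.
#' @slot explainedVar non-increasing, non-negative, length K.
#' @slot rank integer, number of retained components K.
#' @export
setClass("PCAModel", representation(
    scores = "matrix", loadings = "matrix",
    explainedVar = "numeric", rank = "integer"))

setValidity("PCAModel", function(object) {
    msg <- character()
    K <- object@rank
    if (ncol(object@scores) != K || ncol(object@loadings) != K ||
        length(object@explainedVar) != K)
        msg <- c(msg, "scores/loadings/explainedVar disagree on K")
    if (K > 1 && any(diff(object@explainedVar) > 1e-12))
        msg <- c(msg, "explained variance must be non-increasing")
    if (any(object@explainedVar < -1e-12))
        msg <- c(msg, "explained variance must be non-negative")
    if (length(msg)) msg else TRUE
})

#' @describeIn PCAModel summary printout
#' @param object a \code{PCAModel}
#' @export
setMethod("show", "PCAModel", function(object) {
    cat(sprintf("PCAModel: %d strains, %d features, K = %d components\n",
                nrow(object@scores), nrow(object@loadings), object@rank))
    ev <- object@explainedVar
    tot <- sum(ev)
    if (tot > 0)
        cat("explained variance (%):",
            paste(sprintf("%.1f", 100 * utils::head(ev, 5) / tot),
                  collapse = ", "),
            if (object@rank > 5) "..." else "", "\n")
    invisible(NULL)
})

#' @rdname PCAModel-class
#' @param model a \code{PCAModel}
#' @export
pcaScores <- function(model) model@scores

#' @rdname PCAModel-class
#' @export
pcaLoadings <- function(model) model@loadings

#' @rdname PCAModel-class
#' @export
explainedVariance <- function(model) model@explainedVar

#' @rdname PCAModel-class
#' @export
pcaRank <- function(model) model@rank

#' PlaneSelection: the PC plane where a strain stands out
#'
#' Result of [bestPlane()]: the two principal components on which a strain
#' shows the largest separation gaps from every other strain, plus the full
#' per-component gap vector.
#'
#' @slot strainId character label of the strain.
#' @slot plane integer(2), 1-based component indices; \code{plane[1]} is the
#'   component with the largest gap.
#' @slot gaps numeric(2), the gaps for the two chosen components.
#' @slot allGaps numeric(K), gap per component.
#' @export
setClass("PlaneSelection", representation(
    strainId = "character", plane = "integer",
    gaps = "numeric", allGaps = "numeric"))

setValidity("PlaneSelection", function(object) {
    msg <- character()
    if (length(object@plane) != 2 || object@plane[1] == object@plane[2])
        msg <- c(msg, "plane must be two distinct component indices")
    if (length(object@gaps) == 2 && object@gaps[1] < object@gaps[2] - 1e-12)
        msg <- c(msg, "gaps must be ordered: gap_i >= gap_j")
    if (length(msg)) msg else TRUE
})

#' @describeIn PlaneSelection summary printout
#' @param object a \code{PlaneSelection}
#' @export
setMethod("show", "PlaneSelection", function(object) {
    cat(sprintf("PlaneSelection: strain %s stands out in PC%d vs. PC%d\n",
                object@strainId, object@plane[1], object@plane[2]))
    cat(sprintf("gaps: %.4g (PC%d), %.4g (PC%d)\n",
                object@gaps[1], object@plane[1],
                object@gaps[2], object@plane[2]))
    invisible(NULL)
})

#' @rdname PlaneSelection-class
#' @param x a \code{PlaneSelection}
#' @export
selectedPlane <- function(x) x@plane

#' @rdname PlaneSelection-class
#' @export
planeGaps <- function(x) x@allGaps

#' StrainReport: ranked unique features for one strain
#'
#' One entry of the final PoPCAR output. \code{records} is a data.frame
#' with columns \code{rank, rt, mz, distance, pc_i, pc_j, intensity} (plus
#' \code{match_name, match_adduct, match_ppm, novel_flag} after
#' [annotateReport()]), sorted by non-increasing loading distance.
#'
#' @slot strainId character label.
#' @slot plane integer(2) selected PC plane.
#' @slot records data.frame of ranked unique features.
#' @export
setClass("StrainReport", representation(
    strainId = "character", plane = "integer", records = "data.frame"))

setValidity("StrainReport", function(object) {
    msg <- character()
    r <- object@records
    need <- c("rank", "rt", "mz", "distance", "pc_i", "pc_j", "intensity")
    if (!all(need %in% colnames(r)))
        msg <- c(msg, paste("records must have columns:",
                            paste(need, collapse = ", ")))
    else if (nrow(r)) {
        if (any(diff(r$distance) > 1e-12))
            msg <- c(msg, "records must be sorted by non-increasing distance")
        if (!identical(r$rank, seq_len(nrow(r))))
            msg <- c(msg, "ranks must be 1..n in order")
        if (any(r$intensity <= 0))
            msg <- c(msg, "reported intensities must be positive")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn StrainReport summary printout
#' @param object a \code{StrainReport}
#' @export
setMethod("show", "StrainReport", function(object) {
    cat(sprintf("StrainReport: %s (plane PC%d vs. PC%d), %d unique features\n",
                object@strainId, object@plane[1], object@plane[2],
                nrow(object@records)))
    if (nrow(object@records))
        print(utils::head(object@records, 5))
    invisible(NULL)
})

#' @rdname StrainReport-class
#' @param report a \code{StrainReport}
#' @export
reportRecords <- function(report) report@records

#' @rdname StrainReport-class
#' @export
reportStrain <- function(report) report@strainId

#' CompoundDB: a compound-mass database for dereplication
#'
#' Neutral monoisotopic masses with names (and optional molecular
#' formulae), kept sorted by mass so queries can binary-search. Any
#' database exported to the simple CSV schema
#' \code{name, monoisotopic_mass, formula} can be mounted.
#'
#' @slot entries data.frame with columns \code{name} (character),
#'   \code{mass} (Da, monoisotopic, ascending) and \code{formula}
#'   (character, may be NA).
#' @seealso [readCompoundDB()], [matchMass()]
#' @export
setClass("CompoundDB", representation(entries = "data.frame"))

setValidity("CompoundDB", function(object) {
    e <- object@entries
    msg <- character()
    if (!all(c("name", "mass", "formula") %in% colnames(e)))
        msg <- c(msg, "entries needs columns name, mass, formula")
    else if (nrow(e)) {
        if (any(e$mass <= 0)) msg <- c(msg, "masses must be positive")
        if (is.unsorted(e$mass)) msg <- c(msg, "masses must be sorted")
    }
    if (length(msg)) msg else TRUE
})

#' @describeIn CompoundDB summary printout
#' @param object a \code{CompoundDB}
#' @export
setMethod("show", "CompoundDB", function(object) {
    e <- object@entries
    cat(sprintf("CompoundDB: %d entries", nrow(e)))
    if (nrow(e))
        cat(sprintf(", mass range %.4f-%.4f Da", min(e$mass), max(e$mass)))
    cat("\n")
    invisible(NULL)
})

#' @rdname CompoundDB-class
#' @param db a \code{CompoundDB}
#' @export
dbEntries <- function(db) db@entries
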
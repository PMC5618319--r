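#' Fit a PCA model by singular value decomposition
#'
#' Decomposes the (already column-centered) scaled matrix as
#' \eqn{X = U S P^T}; scores are \eqn{T = U S}, loadings \eqn{P} have
#' orthonormal columns, and the variance explained by component k is
#' \eqn{S_k^2/(n-1)}. The number of retained components K is the
#' numerical rank (singular values above \code{1e-10} of the largest),
#' but never fewer than two (when the matrix admits them) so that a PC
#' plane is always defined — trailing zero-variance components carry zero
#' scores. Since SVD signs are arbitrary, each component is flipped so
#' its largest-magnitude loading is positive, making reports reproducible
#' across runs and platforms.
#'
#' @param x numeric matrix (strains x features), column-centered — the
#'   output of [paretoScale()].
#' @return a \linkS4class{PCAModel}.
#' @examples
#' x <- paretoScale(matrix(rnorm(40), 4, 10))
#' fitPCA(x)
#' @export
fitPCA <- function(x) {
    x <- as.matrix(x)
    if (nrow(x) < 2)
        stop("PCA needs at least 2 rows")
    n <- nrow(x)
    sv <- svd(x)
    d <- sv$d
    rank <- if (d[1] > 0) sum(d > 1e-10 * d[1]) else 0L
    K <- max(rank, min(2L, min(dim(x))))
    d <- d[seq_len(K)]
    U <- sv$u[, seq_len(K), drop = FALSE]
    P <- sv$v[, seq_len(K), drop = FALSE]
    ## deterministic sign: largest-|loading| entry of each component > 0
    for (k in seq_len(K)) {
        j <- which.max(abs(P[, k]))
        if (P[j, k] < 0) {
            P[, k] <- -P[, k]
            U[, k] <- -U[, k]
        }
    }
    Tmat <- sweep(U, 2, d, "*")
    rownames(Tmat) <- rownames(x)
    rownames(P) <- colnames(x)
    colnames(Tmat) <- colnames(P) <- paste0("PC", seq_len(K))
    methods::new("PCAModel", scores = Tmat, loadings = P,
                 explainedVar = d^2 / (n - 1), rank = as.integer(K))
}

#' Euclidean loading distance of every feature in a PC plane
#'
#' For a plane (PCi, PCj) the distance of feature f from the origin of
#' the loadings plot is \eqn{d_f = \sqrt{P_{fi}^2 + P_{fj}^2}}. Features
#' common to all strains contribute no variance, sit at the plot center
#' and get distance ~0; features driving a strain's separation sit far
#' out.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param plane integer(2), 1-based component indices.
#' @return numeric vector of non-negative distances, one per feature.
#' @export
loadingDistance <- function(model, plane) {
    plane <- as.integer(plane)
    if (length(plane) != 2 || plane[1] == plane[2])
        stop("plane must be two distinct component indices")
    if (any(plane < 1) || any(plane > model@rank))
        stop("plane components out of range 1..", model@rank)
    P <- model@loadings
    sqrt(P[, plane[1]]^2 + P[, plane[2]]^2)
}

#' Indices of the features with the largest distances
#'
#' @param distances numeric vector (e.g. from [loadingDistance()]).
#' @param topN number of features to return; if larger than the number of
#'   features, all are returned with a warning.
#' @return integer vector of 1-based feature indices, by descending
#'   distance; ties break toward the lower feature index.
#' @export
topDistanceFeatures <- function(distances, topN) {
    stopifnot(topN >= 1)
    if (topN > length(distances)) {
        warning("topN (", topN, ") exceeds the number of features (",
                length(distances), "); returning all")
        topN <- length(distances)
    }
    order(-distances, seq_along(distances))[seq_len(topN)]
}

#' Export scores and loadings as CSV
#'
#' @param model a \linkS4class{PCAModel}.
#' @param scoresPath,loadingsPath output files (either may be NULL).
#' @return invisibly, NULL.
#' @export
exportPCA <- function(model, scoresPath = NULL, loadingsPath = NULL) {
    if (!is.null(scoresPath))
        .writeFullPrecision(
            data.frame(id = rownames(model@scores), model@scores,
                       check.names = FALSE), scoresPath)
    if (!is.null(loadingsPath))
        .writeFullPrecision(
            data.frame(id = rownames(model@loadings), model@loadings,
                       check.names = FALSE), loadingsPath)
    invisible(NULL)
}
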
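#' Separation gap of a strain on one principal component
#'
#' How far a strain's score on one component is from the other strains.
#' The default metric is the nearest-neighbor gap,
#' \eqn{\min_{r \ne s} |T_{s,k} - T_{r,k}|}: a strain only stands out on
#' a component if it is separated from \emph{all} other strains there.
#' The alternative \code{"abs_deviation_from_median"} measures
#' \eqn{|T_{s,k} - \mathrm{median}_{r \ne s} T_{r,k}|}, which is closer
#' to eyeballing a scores plot but can be inflated by a second outlier.
#'
#' @param model a \linkS4class{PCAModel}.
#' @param strain strain row index (integer) or id (character).
#' @param pc 1-based component index.
#' @param metric gap definition, see Details.
#' @return non-negative scalar gap in score units.
#' @export
componentGap <- function(model, strain, pc,
                         metric = c("nearest_neighbor",
                                    "abs_deviation_from_median")) {
    metric <- match.arg(metric)
    s <- .resolveStrain(model, strain)
    if (nrow(model@scores) < 2)
        stop("gap undefined with fewer than 2 strains")
    if (pc < 1 || pc > model@rank)
        stop("component out of range 1..", model@rank)
    t <- model@scores[, pc]
    other <- t[-s]
    switch(metric,
        nearest_neighbor = min(abs(t[s] - other)),
        abs_deviation_from_median = abs(t[s] - stats::median(other)))
}

.resolveStrain <- function(model, strain) {
    if (is.character(strain)) {
        s <- match(strain, rownames(model@scores))
        if (is.na(s)) stop("unknown strain: ", strain)
        s
    } else {
        s <- as.integer(strain)
        if (s < 1 || s > nrow(model@scores))
            stop("strain index out of range")
        s
    }
}

#' Per-strain, per-component gap matrix (scores overview)
#'
#' Computes the separation gap of every strain on every retained
#' component — a textual scores-overview: scanning a strain's row
#' reveals at a glance which PC planes separate it from the rest.
#'
#' @inheritParams componentGap
#' @return numeric matrix, strains x K, non-negative.
#' @export
scoresOverview <- function(model, metric = c("nearest_neighbor",
                                             "abs_deviation_from_median")) {
    metric <- match.arg(metric)
    Tm <- model@scores
    K <- model@rank
    out <- matrix(0, nrow(Tm), K, dimnames = list(rownames(Tm),
                                                  colnames(Tm)))
    for (s in seq_len(nrow(Tm)))
        for (k in seq_len(K))
            out[s, k] <- componentGap(model, s, k, metric)
    out
}

#' Find the PC plane where a strain stands out most
#'
#' Computes the per-component gaps for one strain and selects the plane
#' spanned by the two components with the largest gaps (ties toward the
#' lower component index, which favors higher-variance components).
#' Because any other pair's smaller gap cannot exceed the second-largest
#' gap, this top-2 selection also maximizes \eqn{\min(g_i, g_j)} over all
#' \eqn{K(K-1)/2} planes; \code{method = "exhaustive"} performs that pair
#' search explicitly and is retained as a cross-check.
#'
#' @inheritParams componentGap
#' @param method \code{"top2"} (default) or \code{"exhaustive"}.
#' @return a \linkS4class{PlaneSelection}.
#' @export
bestPlane <- function(model, strain,
                      metric = c("nearest_neighbor",
                                 "abs_deviation_from_median"),
                      method = c("top2", "exhaustive")) {
    metric <- match.arg(metric)
    method <- match.arg(method)
    s <- .resolveStrain(model, strain)
    K <- model@rank
    if (K < 2) stop("plane search needs at least 2 components")
    gaps <- vapply(seq_len(K), function(k)
        componentGap(model, s, k, metric), numeric(1))
    if (method == "top2") {
        ord <- order(-gaps, seq_len(K))
        plane <- ord[1:2]
    } else {
        best <- c(1L, 2L); bestKey <- c(-Inf, -Inf)
        for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
            key <- c(min(gaps[i], gaps[j]), max(gaps[i], gaps[j]))
            if (key[1] > bestKey[1] + 1e-15 ||
                (abs(key[1] - bestKey[1]) <= 1e-15 &&
                 key[2] > bestKey[2] + 1e-15)) {
                bestKey <- key
                best <- c(i, j)
            }
        }
        ## orient: pc_i = larger gap, ties toward lower index
        plane <- if (gaps[best[2]] > gaps[best[1]]) rev(best) else best
    }
    id <- rownames(model@scores)[s]
    methods::new("PlaneSelection",
                 strainId = if (is.null(id)) as.character(s) else id,
                 plane = as.integer(plane),
                 gaps = gaps[plane], allGaps = gaps)
}

#' Export the gap matrix as CSV
#'
#' @param model a \linkS4class{PCAModel}.
#' @param path output CSV (rows = strains, columns = PC1..PCK).
#' @param metric gap metric, see [componentGap()].
#' @return \code{path}, invisibly.
#' @export
exportScoresOverview <- function(model, path,
                                 metric = "nearest_neighbor") {
    g <- scoresOverview(model, metric)
    .writeFullPrecision(
        data.frame(strain = rownames(g), g, check.names = FALSE), path)
    invisible(path)
}
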
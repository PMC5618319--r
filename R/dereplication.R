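## monoisotopic mass of a proton, Da
PROTON_MASS <- 1.007276

#' Adduct rules
#'
#' An adduct rule converts an observed ion m/z to a neutral monoisotopic
#' mass: \eqn{M = mz \times z - shift}. The default set is
#' \code{[M+H]+} only, appropriate for positive-ESI acquisition; sodium,
#' ammonium and doubly protonated forms are available.
#'
#' @param label adduct name, e.g. \code{"[M+H]+"}.
#' @param massShift total mass shift in Da (for \code{[M+H]+}: +1.007276).
#' @param charge positive integer charge state.
#' @return an adduct rule (named list).
#' @export
adductRule <- function(label, massShift, charge = 1L) {
    stopifnot(charge >= 1)
    list(label = label, massShift = massShift, charge = as.integer(charge))
}

#' @rdname adductRule
#' @export
defaultAdducts <- function() list(adductRule("[M+H]+", PROTON_MASS, 1L))

#' @rdname adductRule
#' @export
knownAdducts <- function() list(
    adductRule("[M+H]+",   PROTON_MASS,       1L),
    adductRule("[M+Na]+",  22.989218,         1L),
    adductRule("[M+NH4]+", 18.033823,         1L),
    adductRule("[M+2H]2+", 2 * PROTON_MASS,   2L))

#' Neutral mass from an observed ion
#'
#' \eqn{M = mz \times z - shift}. For \code{[M+H]+} this is simply
#' \code{mz - 1.007276}.
#'
#' @param mz observed mass-to-charge (Th).
#' @param adduct an [adductRule()].
#' @return neutral monoisotopic mass in Da.
#' @examples
#' neutralMass(901.4205, adductRule("[M+H]+", 1.007276))  # 900.4132
#' @export
neutralMass <- function(mz, adduct) {
    M <- mz * adduct$charge - adduct$massShift
    if (any(M <= 0))
        stop("non-positive neutral mass for adduct ", adduct$label)
    M
}

#' Observed ion m/z for a neutral mass (inverse of neutralMass)
#'
#' @param M neutral monoisotopic mass (Da).
#' @param adduct an [adductRule()].
#' @return ion m/z in Th.
#' @export
ionMz <- function(M, adduct) (M + adduct$massShift) / adduct$charge

#' Read a compound-mass database from CSV
#'
#' Schema: \code{name, monoisotopic_mass, formula} (formula optional).
#' Any compound collection exported to this schema can be used for
#' dereplication.
#'
#' @param path CSV file.
#' @return a \linkS4class{CompoundDB}, sorted by mass.
#' @export
readCompoundDB <- function(path) {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    cn <- tolower(colnames(df))
    nameCol <- which(cn == "name")[1]
    massCol <- which(cn %in% c("monoisotopic_mass", "mass",
                               "neutral_mass"))[1]
    if (is.na(nameCol) || is.na(massCol))
        stop("compound DB needs 'name' and 'monoisotopic_mass' columns")
    formulaCol <- which(cn == "formula")[1]
    compoundDB(name = as.character(df[[nameCol]]),
               mass = as.numeric(df[[massCol]]),
               formula = if (!is.na(formulaCol))
                   as.character(df[[formulaCol]]) else NA_character_)
}

#' @rdname readCompoundDB
#' @param name,mass,formula entry vectors (formula recycled if scalar NA).
#' @export
compoundDB <- function(name, mass, formula = NA_character_) {
    e <- data.frame(name = name, mass = mass,
                    formula = rep_len(formula, length(name)),
                    stringsAsFactors = FALSE)
    e <- e[order(e$mass), , drop = FALSE]
    rownames(e) <- NULL
    methods::new("CompoundDB", entries = e)
}

#' Match an observed m/z against the compound database
#'
#' For each adduct rule the neutral mass is computed and all database
#' entries within the ppm tolerance (relative to the database mass, the
#' mass-spectrometry convention) are retrieved by binary search over the
#' sorted mass column. A query matching no entry under any adduct is
#' flagged as putatively novel.
#'
#' @param mz observed ion m/z (scalar).
#' @param db a \linkS4class{CompoundDB}.
#' @param adducts list of [adductRule()]s.
#' @param tolPpm mass tolerance in ppm (> 0). The default 5 ppm is a
#'   conventional Q-TOF identity window, slightly wider than the 4-ppm
#'   bucketing tolerance.
#' @return list with \code{query} (the m/z), \code{matches} (data.frame
#'   \code{name, adduct, ppm_error, mass}, sorted by |ppm_error|) and
#'   \code{novel} (TRUE iff no match).
#' @export
matchMass <- function(mz, db, adducts = defaultAdducts(), tolPpm = 5) {
    stopifnot(tolPpm > 0)
    e <- dbEntries(db)
    if (!nrow(e)) {
        .warnEmptyDB()
        return(list(query = mz,
                    matches = data.frame(name = character(),
                                         adduct = character(),
                                         ppm_error = numeric(),
                                         mass = numeric()),
                    novel = TRUE))
    }
    hits <- list()
    for (ad in adducts) {
        M <- tryCatch(neutralMass(mz, ad), error = function(e) NA_real_)
        if (is.na(M)) next
        ## |M_db - M| / M_db <= tol  <=>  M/(1+tol) <= M_db <= M/(1-tol)
        tol <- tolPpm * 1e-6
        lo <- M / (1 + tol)
        hi <- M / (1 - tol)
        i0 <- findInterval(lo, e$mass, left.open = TRUE) + 1L
        i1 <- findInterval(hi, e$mass)
        if (i1 >= i0) {
            cand <- seq(i0, i1)
            ppm <- (M - e$mass[cand]) / e$mass[cand] * 1e6
            keep <- abs(ppm) <= tolPpm
            if (any(keep))
                hits[[length(hits) + 1L]] <-
                    data.frame(name = e$name[cand[keep]],
                               adduct = ad$label,
                               ppm_error = ppm[keep],
                               mass = e$mass[cand[keep]])
        }
    }
    matches <- if (length(hits)) do.call(rbind, hits)
               else data.frame(name = character(), adduct = character(),
                               ppm_error = numeric(), mass = numeric())
    matches <- matches[order(abs(matches$ppm_error)), , drop = FALSE]
    rownames(matches) <- NULL
    list(query = mz, matches = matches, novel = nrow(matches) == 0)
}

.emptyDBWarned <- new.env(parent = emptyenv())
.warnEmptyDB <- function() {
    if (is.null(.emptyDBWarned$done)) {
        warning("compound database is empty; every query flagged novel")
        .emptyDBWarned$done <- TRUE
    }
}

#' Annotate a strain report with dereplication results
#'
#' Adds the best database match (name, adduct, ppm error) and a novelty
#' flag to every record; record order is unchanged.
#'
#' @param report a \linkS4class{StrainReport}.
#' @param db a \linkS4class{CompoundDB}.
#' @param adducts list of [adductRule()]s.
#' @param tolPpm ppm tolerance, see [matchMass()].
#' @return the annotated \linkS4class{StrainReport}.
#' @export
annotateReport <- function(report, db, adducts = defaultAdducts(),
                           tolPpm = 5) {
    r <- reportRecords(report)
    n <- nrow(r)
    r$match_name <- rep(NA_character_, n)
    r$match_adduct <- rep(NA_character_, n)
    r$match_ppm <- rep(NA_real_, n)
    r$novel_flag <- rep(TRUE, n)
    for (i in seq_len(n)) {
        res <- matchMass(r$mz[i], db, adducts, tolPpm)
        if (!res$novel) {
            r$match_name[i] <- res$matches$name[1]
            r$match_adduct[i] <- res$matches$adduct[1]
            r$match_ppm[i] <- res$matches$ppm_error[1]
            r$novel_flag[i] <- FALSE
        }
    }
    methods::new("StrainReport", strainId = reportStrain(report),
                 plane = report@plane, records = r)
}
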
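#' Read a bucket table from disk
#'
#' Reads a strains-by-buckets intensity table in one of three dialects:
#' \describe{
#'   \item{\code{vendor_txt}}{tab-delimited export with one row per
#'     analysis and compound bucket headers encoding retention time and
#'     m/z, e.g. \code{"Bucket_2.50min_301.1000mz"}. The two floats are
#'     extracted by regex (unit suffixes \code{min}/\code{mz} if present,
#'     otherwise the first two numbers in the header), since export
#'     decoration varies between vendor versions.}
#'   \item{\code{wide_csv}}{same layout, comma-separated.}
#'   \item{\code{long_csv}}{tidy triplets with columns \code{sample, rt,
#'     mz, intensity}; missing (sample, bucket) pairs become 0.}
#' }
#' Strain labels are passed through [cleanLabels()]. Missing cells become
#' intensity 0 (the table is dense; zero encodes absence).
#'
#' @param path input file.
#' @param dialect one of \code{"vendor_txt"}, \code{"wide_csv"},
#'   \code{"long_csv"}.
#' @return a \linkS4class{BucketTable}; \code{metadata()} records the
#'   source path and dialect, and flags tables read with zero strains.
#' @examples
#' tf <- tempfile(fileext = ".txt")
#' writeLines(c(paste("Sample", "Bucket_2.50min_301.1000mz",
#'                    "Bucket_9.65min_1185.7445mz", sep = "\t"),
#'              paste("WMMB-499", "0", "1250", sep = "\t")), tf)
#' readBucketTable(tf, "vendor_txt")
#' @export
readBucketTable <- function(path,
                            dialect = c("vendor_txt", "wide_csv",
                                        "long_csv")) {
    dialect <- match.arg(dialect)
    if (!file.exists(path)) stop("input file not found: ", path)
    meta <- list(source = path, dialect = dialect,
                 history = "read_bucket_table")
    if (dialect == "long_csv") {
        df <- utils::read.csv(path, stringsAsFactors = FALSE)
        need <- c("sample", "rt", "mz", "intensity")
        if (!all(need %in% colnames(df)))
            stop("long_csv requires columns: ", paste(need, collapse = ", "))
        return(.longToBucketTable(df, meta))
    }
    sep <- if (dialect == "vendor_txt") "\t" else ","
    df <- utils::read.delim(path, sep = sep, check.names = FALSE,
                            stringsAsFactors = FALSE)
    if (ncol(df) < 2)
        stop("bucket table needs a label column plus at least one bucket")
    hdr <- colnames(df)[-1]
    keys <- parseBucketHeaders(hdr)
    labels <- if (nrow(df)) cleanLabels(as.character(df[[1]]))
              else character(0)
    vals <- as.matrix(df[, -1, drop = FALSE])
    storage.mode(vals) <- "double"
    vals[is.na(vals)] <- 0
    if (nrow(vals) == 0) meta$empty <- TRUE
    rownames(vals) <- labels
    BucketTable(vals, rt = keys$rt, mz = keys$mz, meta = meta)
}

.longToBucketTable <- function(df, meta) {
    df$sample <- as.character(df$sample)
    key <- featureIds(df$rt, df$mz)
    ukey <- unique(key)
    samples <- cleanLabels(unique(df$sample))
    names(samples) <- unique(df$sample)
    m <- matrix(0, nrow = length(samples), ncol = length(ukey),
                dimnames = list(unname(samples), ukey))
    m[cbind(match(samples[df$sample], rownames(m)), match(key, ukey))] <-
        df$intensity
    first <- !duplicated(key)
    rt <- df$rt[first]
    mz <- df$mz[first]
    ord <- order(rt, mz)               # canonical bucket order
    if (nrow(m) == 0) meta$empty <- TRUE
    BucketTable(m[, ord, drop = FALSE], rt = rt[ord], mz = mz[ord],
                meta = meta)
}

#' Parse bucket column headers into (rt, mz) keys
#'
#' Accepts any decoration around the two numbers; numbers suffixed
#' \code{min} / \code{mz} are taken as retention time / mass-to-charge,
#' otherwise the first two numeric tokens are read as (rt, mz) in order.
#'
#' @param headers character vector of column names.
#' @return data.frame with columns \code{rt}, \code{mz}.
#' @export
parseBucketHeaders <- function(headers) {
    num <- "[0-9]+(?:\\.[0-9]+)?(?:[eE][+-]?[0-9]+)?"
    rt <- mz <- rep(NA_real_, length(headers))
    for (i in seq_along(headers)) {
        h <- headers[i]
        mrt <- regmatches(h, regexpr(paste0("(", num, ")\\s*min"), h,
                                     perl = TRUE))
        mmz <- regmatches(h, regexpr(paste0("(", num, ")\\s*(mz|m/z)"), h,
                                     perl = TRUE))
        if (length(mrt) && length(mmz)) {
            rt[i] <- as.numeric(sub("\\s*min$", "", mrt))
            mz[i] <- as.numeric(sub("\\s*(mz|m/z)$", "", mmz))
        } else {
            toks <- regmatches(h, gregexpr(num, h, perl = TRUE))[[1]]
            if (length(toks) < 2)
                stop("cannot parse bucket header (need rt and m/z): '",
                     h, "'")
            rt[i] <- as.numeric(toks[1])
            mz[i] <- as.numeric(toks[2])
        }
    }
    data.frame(rt = rt, mz = mz)
}

#' Clean strain / bucket labels
#'
#' Strips leading/trailing whitespace, directory paths and file
#' extensions, replaces runs of non-alphanumeric characters with
#' \code{"_"}, trims leading/trailing underscores, and deduplicates
#' repeated labels with a numeric suffix (\code{_2}, \code{_3}, ...).
#' Total and idempotent; order preserved.
#'
#' @param raw character vector of labels.
#' @return character vector, same length, unique.
#' @examples
#' cleanLabels(c("/data/WMMB-499_01.d", "  x.mzML ", "a", "a"))
#' @export
cleanLabels <- function(raw) {
    stopifnot(length(raw) >= 1)
    x <- trimws(as.character(raw))
    x <- basename(x)
    x <- sub("\\.[A-Za-z][A-Za-z0-9]*$", "", x)   # drop one file extension
    x <- gsub("[^A-Za-z0-9]+", "_", x)
    x <- gsub("^_+|_+$", "", x)
    x[!nzchar(x)] <- "X"
    ## dedup with numeric suffixes, re-checking new names for collisions
    out <- character(length(x))
    seen <- new.env(parent = emptyenv())
    for (i in seq_along(x)) {
        base <- x[i]
        cand <- base
        n <- 1L
        while (!is.null(seen[[cand]])) {
            n <- n + 1L
            cand <- paste0(base, "_", n)
        }
        seen[[cand]] <- TRUE
        out[i] <- cand
    }
    out
}

#' Write a bucket table to disk
#'
#' Inverse of [readBucketTable()] for the CSV dialects. Values are written
#' at full precision (15 significant digits) so read/write round-trips
#' reproduce the matrix exactly.
#'
#' @param table a \linkS4class{BucketTable}.
#' @param path output file.
#' @param dialect \code{"wide_csv"} (strains x buckets with compound
#'   headers) or \code{"long_csv"} (sample, rt, mz, intensity triplets;
#'   zero cells omitted).
#' @return \code{path}, invisibly.
#' @export
writeBucketTable <- function(table, path,
                             dialect = c("wide_csv", "long_csv")) {
    dialect <- match.arg(dialect)
    keys <- featureKeys(table)
    m <- intensityMatrix(table)
    if (dialect == "wide_csv") {
        hdr <- sprintf("Bucket_%smin_%smz",
                       formatC(keys$rt, format = "g", digits = 17),
                       formatC(keys$mz, format = "g", digits = 17))
        df <- data.frame(Sample = rownames(m), check.names = FALSE)
        df[hdr] <- as.data.frame(m, check.names = FALSE)
        .writeFullPrecision(df, path)
    } else {
        idx <- which(m > 0, arr.ind = TRUE)
        df <- data.frame(sample = rownames(m)[idx[, 1]],
                         rt = keys$rt[idx[, 2]],
                         mz = keys$mz[idx[, 2]],
                         intensity = m[idx])
        df <- df[order(df$sample, df$rt, df$mz), , drop = FALSE]
        .writeFullPrecision(df, path)
    }
    invisible(path)
}

## write.csv with numeric columns rendered at full double precision
## (17 significant digits round-trip an IEEE double exactly)
.writeFullPrecision <- function(df, path) {
    for (j in seq_along(df))
        if (is.numeric(df[[j]]))
            df[[j]] <- formatC(df[[j]], format = "g", digits = 17)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
}

#' Write per-strain reports
#'
#' Writes the final ranked unique-feature reports. \code{"csv"} produces
#' one long file with a leading \code{strain} column; \code{"csv_dir"}
#' produces one \code{<strain>.csv} per strain inside \code{path}
#' (created if needed). Floats carry 6+ significant decimals so ppm-level
#' distinctions survive the round-trip.
#'
#' @param reports list of \linkS4class{StrainReport} (e.g. from
#'   [runPopcar()]).
#' @param path output file (\code{csv}) or directory (\code{csv_dir}).
#' @param format \code{"csv"} or \code{"csv_dir"}.
#' @return \code{path}, invisibly.
#' @export
writeReport <- function(reports, path, format = c("csv", "csv_dir")) {
    if (identical(format, "xlsx"))
        stop("xlsx output is not supported in this build; ",
             "use format = 'csv' or 'csv_dir'")
    format <- match.arg(format)
    if (is(reports, "StrainReport")) reports <- list(reports)
    stopifnot(length(reports) >= 1)
    cols <- c("rank", "rt", "mz", "distance", "pc_i", "pc_j", "intensity",
              "match_name", "match_adduct", "match_ppm", "novel_flag")
    fill <- function(rep) {
        r <- reportRecords(rep)
        for (cc in setdiff(cols, colnames(r)))
            r[[cc]] <- rep_len(NA, nrow(r))
        r <- r[, cols, drop = FALSE]
        if (nrow(r) == 0) return(r)
        cbind(strain = reportStrain(rep), r)
    }
    if (format == "csv") {
        parts <- lapply(reports, fill)
        parts <- parts[vapply(parts, nrow, 0L) > 0]
        long <- if (length(parts)) do.call(rbind, parts)
                else cbind(data.frame(strain = character()),
                           stats::setNames(
                               as.data.frame(rep(list(numeric()),
                                                 length(cols))), cols))
        .writeFullPrecision(long, path)
    } else {
        if (!dir.exists(path)) dir.create(path, recursive = TRUE)
        for (rep in reports) {
            r <- fill(rep)
            if (nrow(r)) r$strain <- NULL
            else r <- stats::setNames(
                as.data.frame(rep(list(numeric()), length(cols))), cols)
            .writeFullPrecision(
                r, file.path(path, paste0(reportStrain(rep), ".csv")))
        }
    }
    invisible(path)
}
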
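#' @include AllClasses.R
NULL

## Default on-disk dialect: comma-separated, header "time_s,smo2_pct".
## Moxy exports vary across firmware, so column names/indices are remappable.

.warn_rail <- function(values, what = "trace") {
    if (any(values <= 0) || any(values >= 100))
        warning(sprintf(
            "%s touches the device floor/ceiling (0 or 100 a.u.); ",
            what), "clipped stretches can look spuriously stable",
            call. = FALSE)
    invisible(NULL)
}

#' Read one trial's SmO2 CSV into an SmO2Trace
#'
#' Expects a CSV with a time column in seconds and an SmO2 column in percent
#' arbitrary units. The default header is \code{time_s,smo2_pct}; other
#' layouts are absorbed through \code{timeCol}/\code{valueCol} (names or
#' column indices). Values outside [0, 100] are rejected by default or
#' clipped when \code{clip = TRUE}.
#'
#' @param path CSV file path
#' @param subject,muscle,condition trial metadata
#' @param timeCol,valueCol column name or index of the time (s) and SmO2 (%)
#'   columns
#' @param clip clip out-of-range values to [0, 100] instead of rejecting
#' @param smoothed whether the device moving average was already applied
#' @return a validated \linkS4class{SmO2Trace}
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeTrial(SmO2Trace(c(0, 2), c(60, 60)), f)
#' loadTrial(f)
#' @export
loadTrial <- function(path, subject = "unknown",
                      muscle = "vastus_lateralis", condition = "normoxia",
                      timeCol = "time_s", valueCol = "smo2_pct",
                      clip = FALSE, smoothed = TRUE) {
    if (!file.exists(path))
        stop("file not found: ", path)
    df <- tryCatch(
        utils::read.csv(path, stringsAsFactors = FALSE),
        error = function(e) stop("no samples in ", path, ": ",
                                 conditionMessage(e)))
    if (nrow(df) == 0L)
        stop("no samples in ", path)
    pick <- function(col, role) {
        if (is.numeric(col)) {
            if (col > ncol(df)) stop(role, " column index ", col,
                                     " out of range in ", path)
            df[[col]]
        } else {
            if (!col %in% names(df))
                stop(role, " column '", col, "' not found in ", path,
                     " (columns: ", paste(names(df), collapse = ", "), ")")
            df[[col]]
        }
    }
    times <- pick(timeCol, "time")
    values <- pick(valueCol, "value")
    if (!is.numeric(times) || anyNA(times))
        stop("non-numeric time cells in ", path)
    if (!is.numeric(values) || anyNA(values))
        stop("non-numeric SmO2 cells in ", path)
    if (any(diff(times) <= 0))
        stop("non-monotonic time in ", path)
    if (any(values < 0 | values > 100)) {
        if (clip) values <- pmin(pmax(values, 0), 100)
        else stop("SmO2 values outside [0, 100] in ", path,
                  " (set clip = TRUE to clip)")
    }
    .warn_rail(values, basename(path))
    SmO2Trace(times, values, subject = subject, muscle = muscle,
              condition = condition, smoothed = smoothed)
}

#' Write an SmO2Trace to CSV
#'
#' Writes the canonical dialect: header \code{time_s,smo2_pct}, comma
#' separated, values printed with enough digits for exact round-tripping.
#'
#' @param trace a valid \linkS4class{SmO2Trace}
#' @param path output file path
#' @return the path, invisibly
#' @export
writeTrial <- function(trace, path) {
    stopifnot(is(trace, "SmO2Trace"))
    validObject(trace)
    df <- data.frame(time_s = sprintf("%.17g", trace@times),
                     smo2_pct = sprintf("%.17g", trace@values))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    invisible(path)
}

#' Read or validate a cohort manifest
#'
#' A manifest lists one trial per row with columns \code{path},
#' \code{subject_id}, \code{muscle}, \code{condition}; CSV and YAML (a list
#' of records) are both accepted. Duplicate (subject, muscle, condition)
#' triples are rejected.
#'
#' @param manifest file path (CSV/YAML) or a data.frame already in memory
#' @param baseDir directory against which relative trial paths are resolved;
#'   defaults to the manifest's directory
#' @return a validated data.frame with the four manifest columns
#' @export
readManifest <- function(manifest, baseDir = NULL) {
    if (is.character(manifest)) {
        if (!file.exists(manifest))
            stop("manifest not found: ", manifest)
        if (is.null(baseDir)) baseDir <- dirname(manifest)
        if (grepl("\\.ya?ml$", manifest, ignore.case = TRUE)) {
            recs <- yaml::read_yaml(manifest)
            df <- do.call(rbind, lapply(recs, function(r)
                data.frame(path = r$path, subject_id = r$subject_id,
                           muscle = r$muscle, condition = r$condition,
                           stringsAsFactors = FALSE)))
        } else {
            df <- utils::read.csv(manifest, stringsAsFactors = FALSE)
        }
    } else {
        df <- as.data.frame(manifest, stringsAsFactors = FALSE)
        if (is.null(baseDir)) baseDir <- "."
    }
    need <- c("path", "subject_id", "muscle", "condition")
    if (!all(need %in% names(df)))
        stop("manifest must have columns: ", paste(need, collapse = ", "))
    key <- paste(df$subject_id, df$muscle, df$condition, sep = "|")
    if (anyDuplicated(key))
        stop("duplicate (subject, muscle, condition) triple in manifest: ",
             key[duplicated(key)][1])
    abs <- ifelse(grepl("^(/|[A-Za-z]:)", df$path), df$path,
                  file.path(baseDir, df$path))
    df$path <- abs
    missing <- !file.exists(df$path)
    if (any(missing))
        stop("manifest references missing files: ",
             paste(utils::head(df$path[missing], 3), collapse = ", "))
    df
}

#' Load a cohort of trials from a manifest
#'
#' Reads every trial listed in a manifest into an \linkS4class{SmO2Cohort}.
#' In strict mode (default) any per-file failure aborts the whole load with
#' the offending file named; in lenient mode failing files are skipped with
#' a warning.
#'
#' @param manifest path to a manifest file, or a manifest data.frame
#' @param strict abort on the first file error (default) or skip-with-warning
#' @param ... passed to \code{\link{loadTrial}} (e.g. \code{timeCol}, \code{clip})
#' @return an \linkS4class{SmO2Cohort}
#' @seealso \code{\link{cohortGroups}} for muscle-by-condition grouping
#' @export
loadCohort <- function(manifest, strict = TRUE, ...) {
    mf <- readManifest(manifest)
    out <- vector("list", nrow(mf))
    keep <- logical(nrow(mf))
    for (i in seq_len(nrow(mf))) {
        tr <- tryCatch(
            loadTrial(mf$path[i], subject = mf$subject_id[i],
                      muscle = mf$muscle[i], condition = mf$condition[i], ...),
            error = function(e) e)
        if (inherits(tr, "error")) {
            msg <- sprintf("failed to load %s: %s", mf$path[i],
                           conditionMessage(tr))
            if (strict) stop(msg) else { warning(msg, call. = FALSE); next }
        }
        out[[i]] <- tr
        keep[i] <- TRUE
    }
    SmO2Cohort(out[keep])
}

#' Split a cohort into muscle-by-condition groups
#'
#' @param cohort an \linkS4class{SmO2Cohort}
#' @return named list of integer index vectors, one per
#'   \code{muscle.condition} group present in the cohort
#' @export
cohortGroups <- function(cohort) {
    tab <- cohortTable(cohort)
    split(seq_len(nrow(tab)),
          interaction(tab$muscle, tab$condition, drop = TRUE))
}

#' Write a cohort manifest to CSV
#'
#' @param manifest data.frame with columns path, subject_id, muscle, condition
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeManifest <- function(manifest, path) {
    utils::write.csv(
        manifest[, c("path", "subject_id", "muscle", "condition")],
        path, row.names = FALSE, quote = FALSE)
    invisible(path)
}
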
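#' @include AllClasses.R plateau_detection.R agreement_stats.R
NULL

#' Summarise plateau determinations per group per criterion
#'
#' Aggregates a trials-by-criteria determination grid (as returned by
#' \code{classifyAllCriteria} on a cohort) into counts and percentages of
#' plateau-positive trials per muscle-by-condition group, the layout of the
#' study's result tables. Percentages are stored at full precision;
#' count comparisons should use the integer counts, since printed
#' percentages are formatting artifacts (29/30 prints as 96.66).
#'
#' @param determinations logical matrix, trials x criteria, with a
#'   \code{"meta"} attribute (or \code{meta} supplied) carrying per-trial
#'   \code{muscle} and \code{condition}
#' @param meta optional data.frame of per-trial metadata overriding the
#'   attribute
#' @return data.frame with columns criterion, muscle, condition, n_total,
#'   n_plateau, pct_plateau; empty input gives a zero-row frame
#' @export
summarizeCohort <- function(determinations, meta = attr(determinations, "meta")) {
    if (is.null(dim(determinations)))
        determinations <- matrix(determinations, ncol = 1,
                                 dimnames = list(NULL, "criterion"))
    if (nrow(determinations) == 0L)
        return(data.frame(criterion = character(0), muscle = character(0),
                          condition = character(0), n_total = integer(0),
                          n_plateau = integer(0), pct_plateau = numeric(0)))
    if (is.null(meta) || !all(c("muscle", "condition") %in% names(meta)))
        stop("per-trial 'muscle' and 'condition' metadata are required")
    groups <- split(seq_len(nrow(determinations)),
                    interaction(meta$muscle, meta$condition, drop = TRUE,
                                sep = "|"))
    out <- do.call(rbind, lapply(colnames(determinations), function(cid) {
        do.call(rbind, lapply(names(groups), function(g) {
            idx <- groups[[g]]
            mc <- strsplit(g, "|", fixed = TRUE)[[1]]
            n <- length(idx)
            k <- sum(determinations[idx, cid])
            data.frame(criterion = cid, muscle = mc[1], condition = mc[2],
                       n_total = n, n_plateau = k,
                       pct_plateau = if (n > 0) 100 * k / n else NA_real_,
                       stringsAsFactors = FALSE)
        }))
    }))
    rownames(out) <- NULL
    out
}

#' Build the method-comparison matrix
#'
#' Assembles the case-by-case binary grid of plateau determinations across
#' methods (the four threshold criteria plus visual-consensus columns) and
#' the pairwise percent-agreement table between every pair of methods.
#'
#' @param methods named list of logical vectors (one per method), all of the
#'   same length and aligned on the same trials; or a logical matrix with
#'   method columns
#' @param meta optional per-trial metadata (muscle, condition); when given,
#'   pairwise agreement is additionally reported per group
#' @return list with \code{grid} (trials x methods, 0/1), \code{agreement}
#'   (methods x methods percent agreement, 100 on the diagonal) and, when
#'   metadata are supplied, \code{byGroup} (long data.frame of per-group
#'   pairwise agreements)
#' @export
buildComparisonMatrix <- function(methods, meta = NULL) {
    grid <- if (is.matrix(methods)) methods else {
        len <- unique(vapply(methods, length, integer(1)))
        if (length(len) != 1L)
            stop("misaligned methods: vectors differ in length")
        do.call(cbind, methods)
    }
    storage.mode(grid) <- "integer"
    mnames <- colnames(grid)
    agree <- matrix(100, length(mnames), length(mnames),
                    dimnames = list(mnames, mnames))
    for (i in seq_along(mnames))
        for (j in seq_along(mnames))
            if (i != j)
                agree[i, j] <- percentAgreement(grid[, i] == 1L,
                                                grid[, j] == 1L)
    out <- list(grid = grid, agreement = agree)
    if (!is.null(meta)) {
        groups <- split(seq_len(nrow(grid)),
                        interaction(meta$muscle, meta$condition, drop = TRUE,
                                    sep = "|"))
        rows <- list()
        for (g in names(groups)) {
            idx <- groups[[g]]
            mc <- strsplit(g, "|", fixed = TRUE)[[1]]
            for (i in seq_along(mnames)) for (j in seq_along(mnames))
                if (i < j)
                    rows[[length(rows) + 1L]] <- data.frame(
                        muscle = mc[1], condition = mc[2],
                        method_a = mnames[i], method_b = mnames[j],
                        agreement_pct = percentAgreement(
                            grid[idx, i] == 1L, grid[idx, j] == 1L),
                        stringsAsFactors = FALSE)
        }
        out$byGroup <- do.call(rbind, rows)
    }
    out
}

#' Pointwise mean and SD kinetics of a group of aligned traces
#'
#' Computes the per-second mean and sample standard deviation (n - 1
#' denominator) across a group of traces resampled onto the identical 1-Hz
#' grid -- the numeric series behind mean-and-SD-cloud kinetics plots.
#'
#' @param traces list of 1-Hz \linkS4class{SmO2Trace} on the same grid
#' @return data.frame with columns time_s, mean, sd, n; sd is NA when the
#'   group has fewer than 2 traces
#' @examples
#' t1 <- resampleTo1Hz(SmO2Trace(c(0, 2, 4), c(10, 10, 10)))
#' t2 <- resampleTo1Hz(SmO2Trace(c(0, 2, 4), c(20, 20, 20)))
#' meanSdKinetics(list(t1, t2))   # mean 15, sd ~7.071
#' @export
meanSdKinetics <- function(traces) {
    if (length(traces) == 0L) stop("empty trace list")
    grid <- traceTimes(traces[[1]])
    for (tr in traces)
        if (!identical(traceTimes(tr), grid))
            stop("traces are not on an identical time grid; resample first")
    m <- do.call(rbind, lapply(traces, traceValues))
    n <- nrow(m)
    if (n < 2L)
        message("fewer than 2 traces: SD undefined")
    data.frame(
        time_s = grid,
        mean = colMeans(m),
        sd = if (n >= 2L) apply(m, 2, stats::sd) else NA_real_,
        n = n
    )
}
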
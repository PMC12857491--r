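#' @include AllClasses.R AllGenerics.R preprocessing.R
NULL

## Core stability rule shared by windowIsStable and the window scan.
## Returns list(stable, deviation) where deviation is the signed change of
## largest magnitude (anchored) or the range (range metric), in criterion
## units: a.u. for absolute mode, percent of the window's first value for
## relative mode. Bounds are inclusive: |deviation| == T counts as stable.
.assess_window <- function(values, criterion) {
    v0 <- values[1]
    if (criterion@mode == "relative" && v0 == 0)
        stop("relative criterion undefined: window's first value is 0")
    if (criterion@metric == "anchored") {
        dev <- values - v0
        if (criterion@mode == "relative") dev <- 100 * dev / v0
        worst <- dev[which.max(abs(dev))]
        list(stable = max(abs(dev)) <= criterion@threshold, deviation = worst)
    } else {
        rng <- max(values) - min(values)
        dev <- if (criterion@mode == "relative") 100 * rng / v0 else rng
        list(stable = dev <= criterion@threshold, deviation = dev)
    }
}

#' Test whether one window of SmO2 values is stable under a criterion
#'
#' Applies a single criterion to one candidate window. Under the default
#' anchored metric the window is stable iff every sample's change from the
#' window's first value v0 stays within [-T, +T]: in a.u. for absolute mode,
#' or as 100 (v - v0) / v0 for relative mode. Under the range metric the
#' window is stable iff max - min <= T (absolute) or 100 (max - min) / v0
#' <= T (relative). Bounds are inclusive: a deviation of exactly T counts
#' as stable (benefit-of-the-doubt convention).
#'
#' @param window a \linkS4class{Segment} of \code{windowS + 1} values, or a
#'   plain numeric vector of that length
#' @param criterion a \linkS4class{PlateauCriterion}
#' @return list with \code{stable} (logical) and \code{deviation} (the
#'   signed deviation of largest magnitude, in criterion units)
#' @examples
#' a5 <- defaultCriteria()$A5
#' windowIsStable(rep(20, 31), a5)                 # stable, deviation 0
#' windowIsStable(seq(50, 56, length.out = 31), a5) # unstable, +6 a.u.
#' @export
windowIsStable <- function(window, criterion) {
    values <- if (is(window, "Segment")) window@values else as.numeric(window)
    if (length(values) != criterion@windowS + 1L)
        stop(sprintf("window must hold exactly %d values (windowS + 1), got %d",
                     criterion@windowS + 1L, length(values)))
    .assess_window(values, criterion)
}

#' Detect a critical-oxygenation plateau in one trial
#'
#' Scans every candidate window [s, s + windowS] for integer start seconds s
#' from the region start to (region end - windowS) -- with the defaults,
#' s in 135..150, i.e. every 30-s window inside the last 45 s of the effort.
#' The trial is plateau-positive iff any window is stable; the earliest
#' stable window wins and its worst signed deviation is reported. When no
#' window is stable, the least-unstable window's deviation is reported and
#' \code{windowStart} is NA.
#'
#' @param x a 1-Hz \linkS4class{SmO2Trace} covering the criterion's region
#' @param criterion a \linkS4class{PlateauCriterion}
#' @param ... unused
#' @return a \linkS4class{PlateauResult}
#' @examples
#' tr <- resampleTo1Hz(SmO2Trace(seq(-30, 210, 2), rep(20, 121)))
#' detectPlateau(tr, defaultCriteria()$A5)
#' @rdname detectPlateau
#' @export
setMethod("detectPlateau", "SmO2Trace",
function(x, criterion, ...) {
    region <- extractSegment(x, criterion@regionStart, criterion@regionEnd)
    vals <- region@values
    if (all(vals == 0) || all(vals == 100))
        warning("analysis region pinned at the device rail (all ",
                vals[1], "); classification may be spurious", call. = FALSE)
    w <- criterion@windowS
    starts <- criterion@regionStart:(criterion@regionEnd - w)
    best_dev <- NA_real_
    for (s in starts) {
        i <- s - criterion@regionStart + 1L
        res <- .assess_window(vals[i:(i + w)], criterion)
        if (res$stable)
            return(new("PlateauResult", detected = TRUE,
                       windowStart = as.integer(s),
                       maxDeviation = res$deviation, criterion = criterion))
        if (is.na(best_dev) || abs(res$deviation) < abs(best_dev))
            best_dev <- res$deviation
    }
    new("PlateauResult", detected = FALSE, windowStart = NA_integer_,
        maxDeviation = best_dev, criterion = criterion)
})

#' Classify one trial under a battery of criteria
#'
#' Runs \code{\link{detectPlateau}} for each criterion; the default battery
#' is A5, A10, R5, R10 (absolute +/-5 and +/-10 a.u., relative +/-5 and
#' +/-10 percent).
#'
#' @param x a 1-Hz \linkS4class{SmO2Trace}
#' @param criteria named list of \linkS4class{PlateauCriterion}
#' @param ... unused
#' @return named list of \linkS4class{PlateauResult}, one per criterion
#' @rdname classifyAllCriteria
#' @export
setMethod("classifyAllCriteria", "SmO2Trace",
function(x, criteria = defaultCriteria(), ...) {
    lapply(criteria, function(cr) detectPlateau(x, cr))
})

#' Classify every trial of a cohort under a battery of criteria
#'
#' @param x an \linkS4class{SmO2Cohort}; each trial is conditioned with
#'   \code{\link{preprocessTrace}} before detection
#' @param criteria named list of criteria (default A5/A10/R5/R10)
#' @param ... passed to \code{\link{preprocessTrace}}
#' @return logical matrix, trials x criteria, of plateau determinations,
#'   with per-trial metadata attached as attribute \code{"meta"}
#' @rdname classifyAllCriteria
#' @export
setMethod("classifyAllCriteria", "SmO2Cohort",
function(x, criteria = defaultCriteria(), ...) {
    res <- t(vapply(trials(x), function(tr) {
        pp <- preprocessTrace(tr, ...)
        vapply(criteria, function(cr) isDetected(detectPlateau(pp, cr)),
               logical(1))
    }, logical(length(criteria))))
    colnames(res) <- names(criteria)
    rownames(res) <- vapply(trials(x), function(tr)
        paste(subjectId(tr), muscleSite(tr), oxygenCondition(tr), sep = "_"),
        character(1))
    attr(res, "meta") <- cohortTable(x)
    res
})
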
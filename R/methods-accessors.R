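#' @include AllGenerics.R
NULL

#' Accessors for SmO2Trace objects
#'
#' @param x an \linkS4class{SmO2Trace}
#' @return \code{traceTimes}/\code{traceValues}: numeric vectors;
#'   \code{subjectId}, \code{muscleSite}, \code{oxygenCondition}: character;
#'   \code{nominalDt}: seconds between samples; \code{isSmoothed}: logical.
#' @examples
#' tr <- SmO2Trace(0:5, rep(50, 6))
#' traceValues(tr)
#' nominalDt(tr)
#' @name SmO2Trace-accessors
NULL

#' @rdname SmO2Trace-accessors
setMethod("traceTimes", "SmO2Trace", function(x) x@times)
#' @rdname SmO2Trace-accessors
setMethod("traceValues", "SmO2Trace", function(x) x@values)
#' @rdname SmO2Trace-accessors
setMethod("subjectId", "SmO2Trace", function(x) x@subject)
#' @rdname SmO2Trace-accessors
setMethod("muscleSite", "SmO2Trace", function(x) x@muscle)
#' @rdname SmO2Trace-accessors
setMethod("oxygenCondition", "SmO2Trace", function(x) x@condition)
#' @rdname SmO2Trace-accessors
setMethod("nominalDt", "SmO2Trace", function(x) x@nominalDt)
#' @rdname SmO2Trace-accessors
setMethod("isSmoothed", "SmO2Trace", function(x) x@smoothed)

#' @rdname PlateauResult-accessors
setMethod("isDetected", "PlateauResult", function(x) x@detected)
#' @rdname PlateauResult-accessors
setMethod("windowStart", "PlateauResult", function(x) x@windowStart)
#' @rdname PlateauResult-accessors
setMethod("maxDeviation", "PlateauResult", function(x) x@maxDeviation)

#' @rdname SmO2Cohort-accessors
setMethod("trials", "SmO2Cohort", function(x) x@trials)
#' @rdname SmO2Cohort-accessors
setMethod("truthLabels", "SmO2Cohort", function(x) x@truth)
#' @rdname SmO2Cohort-accessors
setMethod("trials", "LabeledTrial", function(x) list(x@trace))
#' @rdname SmO2Cohort-accessors
setMethod("truthLabels", "LabeledTrial", function(x) x@truthPlateau)

#' @rdname SmO2Cohort-accessors
setMethod("cohortTable", "SmO2Cohort", function(x) {
    data.frame(
        subject   = vapply(x@trials, subjectId, character(1)),
        muscle    = vapply(x@trials, muscleSite, character(1)),
        condition = vapply(x@trials, oxygenCondition, character(1)),
        truth     = x@truth,
        stringsAsFactors = FALSE
    )
})

#' Number of trials in a cohort
#' @param x an \linkS4class{SmO2Cohort}
#' @export
setMethod("length", "SmO2Cohort", function(x) length(x@trials))

#' Extract one trial from a cohort
#' @param x an \linkS4class{SmO2Cohort}
#' @param i trial index
#' @export
setMethod("[[", "SmO2Cohort", function(x, i) x@trials[[i]])

setMethod("show", "SmO2Trace", function(object) {
    n <- length(object@times)
    rng <- if (n) sprintf("[%.0f, %.0f] s", min(object@times),
                          max(object@times)) else "(empty)"
    cat(sprintf("SmO2Trace: subject %s, %s, %s\n", object@subject,
                object@muscle, object@condition))
    cat(sprintf("  %d samples over %s, dt = %g s, smoothed = %s\n",
                n, rng, object@nominalDt, object@smoothed))
    if (n)
        cat(sprintf("  SmO2 range: %.1f-%.1f a.u.\n",
                    min(object@values), max(object@values)))
})

setMethod("show", "PlateauCriterion", function(object) {
    unit <- if (object@mode == "absolute") "a.u." else "%"
    cat(sprintf(
        "PlateauCriterion %s: %s +/-%g %s, %d-s window in [%d, %d] s (%s)\n",
        object@id, object@mode, object@threshold, unit, object@windowS,
        object@regionStart, object@regionEnd, object@metric))
})

setMethod("show", "PlateauResult", function(object) {
    cat(sprintf("PlateauResult [%s]: %s", object@criterion@id,
                if (object@detected) "plateau detected" else "no plateau"))
    if (!is.na(object@windowStart))
        cat(sprintf(" (window [%d, %d] s, worst deviation %+.2f)",
                    object@windowStart,
                    object@windowStart + object@criterion@windowS,
                    object@maxDeviation))
    cat("\n")
})

setMethod("show", "RatingMatrix", function(object) {
    cat(sprintf("RatingMatrix: %d trials x %d raters (%s)\n",
                nrow(object@ratings), ncol(object@ratings),
                object@raterClass))
    cat(sprintf("  positive ratings per rater: %s\n",
                paste(colSums(object@ratings), collapse = ", ")))
})

setMethod("show", "AgreementResult", function(object) {
    k <- if (is.na(object@kappa)) "undefined" else sprintf("%.3f", object@kappa)
    cat(sprintf("Fleiss' kappa = %s (%s), %d items x %d raters\n",
                k, object@band, object@nItems, object@nRaters))
})

setMethod("show", "SmO2Cohort", function(object) {
    tab <- cohortTable(object)
    cat(sprintf("SmO2Cohort: %d trials\n", nrow(tab)))
    if (nrow(tab))
        print(table(muscle = tab$muscle, condition = tab$condition))
})

setMethod("show", "LabeledTrial", function(object) {
    cat(sprintf("LabeledTrial (truth plateau: %s)\n", object@truthPlateau))
    show(object@trace)
})
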
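#' @include AllClasses.R
NULL

#' @rdname SmO2Trace-accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("muscleSite", function(x) standardGeneric("muscleSite"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("oxygenCondition", function(x) standardGeneric("oxygenCondition"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("nominalDt", function(x) standardGeneric("nominalDt"))
#' @rdname SmO2Trace-accessors
#' @export
setGeneric("isSmoothed", function(x) standardGeneric("isSmoothed"))

#' @rdname movingAverage
#' @export
setGeneric("movingAverage",
    function(x, width = 5, center = FALSE, force = FALSE)
        standardGeneric("movingAverage"))

#' @rdname resampleTo1Hz
#' @export
setGeneric("resampleTo1Hz",
    function(x, maxGapS = 4, method = c("linear", "constant"))
        standardGeneric("resampleTo1Hz"))

#' @rdname extractSegment
#' @export
setGeneric("extractSegment",
    function(x, startS, endS) standardGeneric("extractSegment"))

#' @rdname detectPlateau
#' @export
setGeneric("detectPlateau",
    function(x, criterion, ...) standardGeneric("detectPlateau"))

#' @rdname classifyAllCriteria
#' @export
setGeneric("classifyAllCriteria",
    function(x, criteria = defaultCriteria(), ...)
        standardGeneric("classifyAllCriteria"))

#' @rdname fleissKappa
#' @export
setGeneric("fleissKappa", function(x) standardGeneric("fleissKappa"))

#' @rdname consensusVote
#' @export
setGeneric("consensusVote",
    function(x, minAgree = 3L) standardGeneric("consensusVote"))

#' Accessors for plateau detection results
#'
#' @param x a \linkS4class{PlateauResult}
#' @return \code{isDetected}: logical; \code{windowStart}: integer start
#'   second of the reported window (NA when no stable window exists);
#'   \code{maxDeviation}: the signed worst-case deviation in criterion units.
#' @name PlateauResult-accessors
NULL

#' @rdname PlateauResult-accessors
#' @export
setGeneric("isDetected", function(x) standardGeneric("isDetected"))
#' @rdname PlateauResult-accessors
#' @export
setGeneric("windowStart", function(x) standardGeneric("windowStart"))
#' @rdname PlateauResult-accessors
#' @export
setGeneric("maxDeviation", function(x) standardGeneric("maxDeviation"))

#' Accessors for cohorts and labelled trials
#'
#' @param x an \linkS4class{SmO2Cohort} or \linkS4class{LabeledTrial}
#' @return \code{trials}: the list of traces; \code{truthLabels}: logical
#'   ground-truth labels; \code{cohortTable}: a data.frame of per-trial
#'   metadata (subject, muscle, condition, truth).
#' @name SmO2Cohort-accessors
NULL

#' @rdname SmO2Cohort-accessors
#' @export
setGeneric("trials", function(x) standardGeneric("trials"))
#' @rdname SmO2Cohort-accessors
#' @export
setGeneric("truthLabels", function(x) standardGeneric("truthLabels"))
#' @rdname SmO2Cohort-accessors
#' @export
setGeneric("cohortTable", function(x) standardGeneric("cohortTable"))
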
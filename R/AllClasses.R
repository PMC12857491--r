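#' @import methods
NULL

.MUSCLES <- c("vastus_lateralis", "triceps_brachii")
.CONDITIONS <- c("normoxia", "hypoxia")

#' SmO2Trace: a single trial's muscle-oxygen-saturation time series
#'
#' One trial of wearable-NIRS muscle oxygen saturation (SmO2, percent in
#' arbitrary units on a 0--100 scale) with acquisition metadata. Time is in
#' seconds relative to test start: the 3-min all-out test spans 0--180 s and a
#' full 4-min sample spans -30 to +210 s (30 s pre-test, 180 s test, 30 s
#' recovery). Every pipeline stage consumes and returns this class.
#'
#' @slot subject opaque subject identifier
#' @slot muscle measurement site, \code{"vastus_lateralis"} or
#'   \code{"triceps_brachii"}
#' @slot condition oxygen availability, \code{"normoxia"} or \code{"hypoxia"}
#' @slot times sample times in seconds, strictly increasing
#' @slot values SmO2 in percent arbitrary units, each within [0, 100]
#' @slot nominalDt nominal sampling interval in seconds (> 0)
#' @slot smoothed whether the device 5-s moving average has been applied
#' @exportClass SmO2Trace
setClass("SmO2Trace",
    representation(
        subject   = "character",
        muscle    = "character",
        condition = "character",
        times     = "numeric",
        values    = "numeric",
        nominalDt = "numeric",
        smoothed  = "logical"
    ),
    prototype(
        subject = "unknown", muscle = "vastus_lateralis",
        condition = "normoxia", nominalDt = 2, smoothed = TRUE
    )
)

setValidity("SmO2Trace", function(object) {
    msg <- character(0)
    if (length(object@times) != length(object@values))
        msg <- c(msg, "'times' and 'values' must have equal length")
    if (length(object@times) > 0L && any(diff(object@times) <= 0))
        msg <- c(msg, "'times' must be strictly increasing")
    if (length(object@values) > 0L &&
        (anyNA(object@values) ||
         any(object@values < 0) || any(object@values > 100)))
        msg <- c(msg, "'values' must lie within [0, 100] and contain no NA")
    if (length(object@nominalDt) != 1L || is.na(object@nominalDt) ||
        object@nominalDt <= 0)
        msg <- c(msg, "'nominalDt' must be a single positive number")
    if (!object@muscle %in% .MUSCLES)
        msg <- c(msg, sprintf("'muscle' must be one of: %s",
                              paste(.MUSCLES, collapse = ", ")))
    if (!object@condition %in% .CONDITIONS)
        msg <- c(msg, sprintf("'condition' must be one of: %s",
                              paste(.CONDITIONS, collapse = ", ")))
    if (length(msg)) msg else TRUE
})

#' Construct an SmO2Trace
#'
#' @param times numeric vector of sample times (s), strictly increasing
#' @param values numeric vector of SmO2 values (percent a.u., 0--100)
#' @param subject subject identifier
#' @param muscle \code{"vastus_lateralis"} or \code{"triceps_brachii"}
#' @param condition \code{"normoxia"} or \code{"hypoxia"}
#' @param nominalDt nominal sampling interval in seconds; inferred as the
#'   median time step when missing
#' @param smoothed logical; has the device 5-s moving average been applied
#' @return a validated \linkS4class{SmO2Trace}
#' @examples
#' tr <- SmO2Trace(times = seq(-30, 210, by = 2),
#'                 values = rep(60, 121), subject = "S01")
#' tr
#' @export
SmO2Trace <- function(times, values, subject = "unknown",
                      muscle = "vastus_lateralis", condition = "normoxia",
                      nominalDt = NULL, smoothed = TRUE) {
    times <- as.numeric(times)
    values <- as.numeric(values)
    if (is.null(nominalDt)) {
        nominalDt <- if (length(times) >= 2L)
            stats::median(diff(times)) else 1
    }
    new("SmO2Trace", subject = as.character(subject), muscle = muscle,
        condition = condition, times = times, values = values,
        nominalDt = as.numeric(nominalDt), smoothed = smoothed)
}

#' Segment: an inclusive 1-Hz slice of a trace
#'
#' A contiguous stretch of a 1-Hz resampled trace with inclusive integer
#' second bounds: the segment [a, b] carries b - a + 1 samples, so a 30-s
#' analysis window holds 31 values and the 45-s terminal region holds 46.
#'
#' @slot startS first second (inclusive)
#' @slot endS last second (inclusive)
#' @slot values SmO2 values on the integer-second grid
#' @exportClass Segment
setClass("Segment",
    representation(startS = "integer", endS = "integer", values = "numeric"))

setValidity("Segment", function(object) {
    msg <- character(0)
    if (object@endS < object@startS)
        msg <- c(msg, "'endS' must be >= 'startS'")
    if (length(object@values) != object@endS - object@startS + 1L)
        msg <- c(msg, "length(values) must equal endS - startS + 1")
    if (anyNA(object@values) ||
        any(object@values < 0) || any(object@values > 100))
        msg <- c(msg, "'values' must lie within [0, 100]")
    if (length(msg)) msg else TRUE
})

#' PlateauCriterion: a parameterised plateau detection rule
#'
#' A sliding-window stability rule. In \code{"absolute"} mode the threshold is
#' in a.u. of percent SmO2; in \code{"relative"} mode it is a percentage of
#' the window's first value. The \code{"anchored"} metric requires every
#' sample's change from the window's first value to stay within [-T, +T]
#' (bounds inclusive); the \code{"range"} metric requires max - min <= T.
#'
#' @slot id short identifier, e.g. "A5"
#' @slot mode \code{"absolute"} or \code{"relative"}
#' @slot threshold positive threshold magnitude T
#' @slot windowS window length in seconds (default 30)
#' @slot regionStart,regionEnd search region in seconds (default 135--180,
#'   the last 45 s of the effort)
#' @slot metric \code{"anchored"} or \code{"range"}
#' @exportClass PlateauCriterion
setClass("PlateauCriterion",
    representation(
        id = "character", mode = "character", threshold = "numeric",
        windowS = "integer", regionStart = "integer", regionEnd = "integer",
        metric = "character"
    ))

setValidity("PlateauCriterion", function(object) {
    msg <- character(0)
    if (!object@mode %in% c("absolute", "relative"))
        msg <- c(msg, "'mode' must be \"absolute\" or \"relative\"")
    if (!object@metric %in% c("anchored", "range"))
        msg <- c(msg, "'metric' must be \"anchored\" or \"range\"")
    if (length(object@threshold) != 1L || is.na(object@threshold) ||
        object@threshold <= 0)
        msg <- c(msg, "'threshold' must be a single positive number")
    if (object@windowS > object@regionEnd - object@regionStart)
        msg <- c(msg, "'windowS' must not exceed the region length")
    if (length(msg)) msg else TRUE
})

#' Construct a PlateauCriterion
#'
#' @param mode \code{"absolute"} (threshold in a.u.) or \code{"relative"}
#'   (threshold in percent of the window's first value)
#' @param threshold positive threshold magnitude
#' @param windowS window length in seconds
#' @param region numeric length-2, search region in seconds
#' @param metric \code{"anchored"} (default) or \code{"range"}
#' @param id short identifier; derived from mode/threshold when missing
#' @return a \linkS4class{PlateauCriterion}
#' @examples
#' plateauCriterion("absolute", 5)           # the A5 rule
#' plateauCriterion("relative", 10)          # the R10 rule
#' @export
plateauCriterion <- function(mode = c("absolute", "relative"), threshold,
                             windowS = 30L, region = c(135L, 180L),
                             metric = c("anchored", "range"), id = NULL) {
    mode <- match.arg(mode)
    metric <- match.arg(metric)
    if (is.null(id))
        id <- paste0(if (mode == "absolute") "A" else "R",
                     format(threshold, trim = TRUE))
    new("PlateauCriterion", id = id, mode = mode,
        threshold = as.numeric(threshold), windowS = as.integer(windowS),
        regionStart = as.integer(region[1]), regionEnd = as.integer(region[2]),
        metric = metric)
}

#' The default criterion battery: A5, A10, R5, R10
#'
#' Absolute thresholds of +/-5 and +/-10 a.u. of percent SmO2 and relative
#' thresholds of +/-5 and +/-10 percent of the window's first value, each over
#' a 30-s window sliding in the last 45 s of the effort.
#'
#' @param metric stability metric for all four criteria
#' @return named list of \linkS4class{PlateauCriterion} with ids
#'   \code{A5, A10, R5, R10}
#' @examples
#' names(defaultCriteria())
#' @export
defaultCriteria <- function(metric = c("anchored", "range")) {
    metric <- match.arg(metric)
    list(
        A5  = plateauCriterion("absolute",  5, metric = metric, id = "A5"),
        A10 = plateauCriterion("absolute", 10, metric = metric, id = "A10"),
        R5  = plateauCriterion("relative",  5, metric = metric, id = "R5"),
        R10 = plateauCriterion("relative", 10, metric = metric, id = "R10")
    )
}

#' PlateauResult: the outcome of one criterion on one trial
#'
#' @slot detected was any candidate window stable
#' @slot windowStart start second of the earliest stable window (NA when not
#'   detected; then the least-unstable window's deviation is reported)
#' @slot maxDeviation signed deviation of largest magnitude in the reported
#'   window, in the criterion's units (a.u. or percent)
#' @slot criterion the rule that produced this result
#' @exportClass PlateauResult
setClass("PlateauResult",
    representation(
        detected = "logical", windowStart = "integer",
        maxDeviation = "numeric", criterion = "PlateauCriterion"
    ))

setValidity("PlateauResult", function(object) {
    msg <- character(0)
    cr <- object@criterion
    if (object@detected) {
        if (is.na(object@windowStart) ||
            object@windowStart < cr@regionStart ||
            object@windowStart > cr@regionEnd - cr@windowS)
            msg <- c(msg, "detected result must carry a windowStart inside the region")
        if (abs(object@maxDeviation) > cr@threshold + 1e-9)
            msg <- c(msg, "detected result must have |maxDeviation| <= threshold")
    }
    if (length(msg)) msg else TRUE
})

#' RatingMatrix: binary plateau annotations, trials x raters
#'
#' Complete (no missing cells) binary ratings of plateau existence from a
#' panel of raters; feeds Fleiss' kappa and majority-vote consensus.
#'
#' @slot ratings integer matrix of 0/1, rows = trials, columns = raters
#' @slot raterClass \code{"expert"} or \code{"non_expert"}
#' @exportClass RatingMatrix
setClass("RatingMatrix",
    representation(ratings = "matrix", raterClass = "character"),
    prototype(raterClass = "expert"))

setValidity("RatingMatrix", function(object) {
    msg <- character(0)
    r <- object@ratings
    if (nrow(r) < 1L) msg <- c(msg, "at least one item (trial) is required")
    if (ncol(r) < 2L) msg <- c(msg, "at least two raters are required")
    if (anyNA(r)) msg <- c(msg, "rating matrix must be complete (no NA cells)")
    else if (!all(r %in% c(0L, 1L)))
        msg <- c(msg, "ratings must be binary (0/1)")
    if (!object@raterClass %in% c("expert", "non_expert"))
        msg <- c(msg, "'raterClass' must be \"expert\" or \"non_expert\"")
    if (length(msg)) msg else TRUE
})

#' Construct a RatingMatrix
#'
#' @param ratings matrix (or data.frame) of binary ratings, trials in rows,
#'   raters in columns; logical, 0/1, or "yes"/"no"
#' @param raterClass \code{"expert"} or \code{"non_expert"}
#' @return a \linkS4class{RatingMatrix}
#' @examples
#' m <- ratingMatrix(rbind(c(1, 1, 1, 0), c(0, 0, 0, 0)))
#' m
#' @export
ratingMatrix <- function(ratings, raterClass = "expert") {
    ratings <- as.matrix(ratings)
    if (is.character(ratings)) {
        low <- tolower(ratings)
        if (!all(low %in% c("yes", "no")))
            stop("character ratings must be \"yes\"/\"no\"")
        ratings <- matrix(as.integer(low == "yes"), nrow = nrow(low),
                          dimnames = dimnames(low))
    }
    storage.mode(ratings) <- "integer"
    if (is.null(rownames(ratings)))
        rownames(ratings) <- sprintf("trial_%02d", seq_len(nrow(ratings)))
    if (is.null(colnames(ratings)))
        colnames(ratings) <- sprintf("rater_%d", seq_len(ncol(ratings)))
    new("RatingMatrix", ratings = ratings, raterClass = raterClass)
}

#' AgreementResult: Fleiss' kappa with its interpretation band
#'
#' @slot kappa chance-corrected agreement in [-1, 1], or NA when undefined
#'   (all ratings in a single category so expected agreement is 1)
#' @slot band Landis-Koch label, or "undefined"
#' @slot nItems,nRaters dimensions of the rating matrix
#' @exportClass AgreementResult
setClass("AgreementResult",
    representation(kappa = "numeric", band = "character",
                   nItems = "integer", nRaters = "integer"))

#' SyntheticParams: generative parameters for one synthetic trial
#'
#' Parameters of the synthetic SmO2 backbone: baseline before effort onset,
#' mono-exponential desaturation with time constant \code{tauDrop} toward the
#' plateau level, optional late linear drift over the analysis region
#' [135, 180] s (the plateau-breaking control), exponential reoxygenation
#' after 180 s, additive Gaussian noise, and movement-artifact pulses.
#'
#' @slot baseline pre-test SmO2 (a.u.)
#' @slot plateauLevel end-test asymptote (a.u.)
#' @slot onsetS effort onset time (s)
#' @slot tauDrop desaturation time constant (s)
#' @slot driftSlope late drift in a.u./s applied over [135, 180]; 0 for a
#'   true-plateau trial
#' @slot noiseSd Gaussian noise SD (a.u.)
#' @slot reoxyTau reoxygenation time constant (s) after 180 s
#' @slot artifacts data.frame with columns time, magnitude, duration
#' @slot sampleDt sampling interval (s)
#' @slot seed RNG seed for the noise realisation
#' @exportClass SyntheticParams
setClass("SyntheticParams",
    representation(
        baseline = "numeric", plateauLevel = "numeric", onsetS = "numeric",
        tauDrop = "numeric", driftSlope = "numeric", noiseSd = "numeric",
        reoxyTau = "numeric", artifacts = "data.frame", sampleDt = "numeric",
        seed = "integer"
    ))

setValidity("SyntheticParams", function(object) {
    msg <- character(0)
    if (!(object@plateauLevel >= 0 && object@plateauLevel < object@baseline &&
          object@baseline <= 100))
        msg <- c(msg, "need 0 <= plateauLevel < baseline <= 100")
    if (object@tauDrop <= 0) msg <- c(msg, "'tauDrop' must be positive")
    if (object@noiseSd < 0) msg <- c(msg, "'noiseSd' must be >= 0")
    if (object@sampleDt <= 0) msg <- c(msg, "'sampleDt' must be positive")
    if (nrow(object@artifacts) &&
        !all(c("time", "magnitude", "duration") %in% names(object@artifacts)))
        msg <- c(msg, "'artifacts' needs columns time, magnitude, duration")
    if (length(msg)) msg else TRUE
})

#' Construct SyntheticParams
#'
#' Defaults emulate the study conditions: baselines around 60--75 a.u.,
#' plateau levels in the 10--22 a.u. band spanned by the printed group means,
#' a ~15-s desaturation time constant, 2-s sampling and 1 a.u. noise.
#'
#' @param baseline pre-test SmO2 (a.u.), default 65
#' @param plateauLevel end-test asymptote (a.u.), default 16
#' @param onsetS effort onset (s), default 0
#' @param tauDrop desaturation time constant (s), default 15
#' @param driftSlope a.u./s over [135, 180], default 0 (true plateau)
#' @param noiseSd noise SD (a.u.), default 1
#' @param reoxyTau recovery time constant (s), default 20
#' @param artifacts data.frame(time, magnitude, duration) of movement pulses
#' @param sampleDt sampling interval (s), default 2
#' @param seed integer RNG seed
#' @return a \linkS4class{SyntheticParams}
#' @examples
#' syntheticParams(plateauLevel = 21, seed = 1)
#' @export
syntheticParams <- function(baseline = 65, plateauLevel = 16, onsetS = 0,
                            tauDrop = 15, driftSlope = 0, noiseSd = 1,
                            reoxyTau = 20,
                            artifacts = data.frame(time = numeric(0),
                                                   magnitude = numeric(0),
                                                   duration = numeric(0)),
                            sampleDt = 2, seed = 1L) {
    new("SyntheticParams", baseline = baseline, plateauLevel = plateauLevel,
        onsetS = onsetS, tauDrop = tauDrop, driftSlope = driftSlope,
        noiseSd = noiseSd, reoxyTau = reoxyTau, artifacts = artifacts,
        sampleDt = sampleDt, seed = as.integer(seed))
}

#' LabeledTrial: a synthetic trace plus its ground-truth plateau label
#'
#' The truth label is computed on the noise-free backbone (never the noisy
#' realisation) under a fixed labelling criterion, so it is a deterministic
#' function of the parameters.
#'
#' @slot trace the noisy sampled \linkS4class{SmO2Trace}
#' @slot truthPlateau ground-truth plateau label
#' @slot params generating \linkS4class{SyntheticParams}
#' @exportClass LabeledTrial
setClass("LabeledTrial",
    representation(trace = "SmO2Trace", truthPlateau = "logical",
                   params = "SyntheticParams"))

#' SmO2Cohort: a collection of trials with metadata (and optional labels)
#'
#' @slot trials list of \linkS4class{SmO2Trace}
#' @slot truth logical vector of ground-truth labels (NA when unknown)
#' @exportClass SmO2Cohort
setClass("SmO2Cohort",
    representation(trials = "list", truth = "logical"))

setValidity("SmO2Cohort", function(object) {
    msg <- character(0)
    if (!all(vapply(object@trials, is, logical(1), class2 = "SmO2Trace")))
        msg <- c(msg, "'trials' must be a list of SmO2Trace objects")
    if (length(object@truth) != length(object@trials))
        msg <- c(msg, "'truth' must have one entry per trial")
    if (length(msg)) msg else TRUE
})

#' Construct an SmO2Cohort
#'
#' @param trials list of \linkS4class{SmO2Trace}
#' @param truth optional logical ground-truth labels (default all NA)
#' @return an \linkS4class{SmO2Cohort}
#' @export
SmO2Cohort <- function(trials, truth = rep(NA, length(trials))) {
    new("SmO2Cohort", trials = trials, truth = as.logical(truth))
}
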
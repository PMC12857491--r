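#' @include AllClasses.R AllGenerics.R
NULL

#' Trailing moving average of an SmO2 trace
#'
#' Smooths the signal with a time-based moving average: each output sample is
#' the mean of all input samples in the half-open trailing window
#' (t - width, t], i.e. within the preceding \code{width} seconds and
#' inclusive of the current sample (causal, matching a real-time device
#' filter; a width equal to the sampling interval is the identity). Support
#' shortens at the left edge, where fewer samples are available. A centred
#' window is available via \code{center = TRUE} for sensitivity analyses.
#'
#' Traces already flagged as device-smoothed are returned unchanged (the
#' double-smoothing guard) unless \code{force = TRUE}.
#'
#' @param x an \linkS4class{SmO2Trace}
#' @param width window width in seconds (default 5, the Moxy firmware
#'   default); must be positive and at least the sampling interval
#' @param center use a centred window of half-width \code{width/2}
#' @param force re-smooth even when \code{isSmoothed(x)} is TRUE
#' @return a smoothed \linkS4class{SmO2Trace} with \code{smoothed = TRUE}
#' @examples
#' tr <- SmO2Trace(seq(0, 20, 2), rep(40, 11), smoothed = FALSE)
#' traceValues(movingAverage(tr))   # constant in, constant out
#' @rdname movingAverage
#' @export
setMethod("movingAverage", "SmO2Trace",
function(x, width = 5, center = FALSE, force = FALSE) {
    if (width <= 0) stop("'width' must be positive")
    if (width < x@nominalDt)
        stop("'width' must be at least the sampling interval (",
             x@nominalDt, " s)")
    if (x@smoothed && !force)
        return(x)
    t <- x@times; v <- x@values
    out <- if (center) {
        vapply(seq_along(t), function(i)
            mean(v[t >= t[i] - width / 2 & t <= t[i] + width / 2]),
            numeric(1))
    } else {
        ## trailing window (t - width, t]: half-open on the left so that
        ## width equal to the sampling interval is the identity
        vapply(seq_along(t), function(i)
            mean(v[t > t[i] - width & t <= t[i]]), numeric(1))
    }
    initialize(x, values = out, smoothed = TRUE)
})

#' Resample an SmO2 trace onto the 1-Hz integer-second grid
#'
#' Linear interpolation of the signal onto every integer second covered by
#' the data: the output grid spans [ceiling(first time), floor(last time)].
#' No extrapolation is performed outside the sampled range -- inventing
#' values for a bounded physiological signal would fabricate data. Internal
#' gaps wider than \code{maxGapS} abort with the gap identified.
#'
#' @param x an \linkS4class{SmO2Trace} with at least 2 samples
#' @param maxGapS largest tolerated gap between consecutive samples (s)
#' @param method interpolation rule: \code{"linear"} (default) or
#'   \code{"constant"} (last observation carried forward)
#' @return a 1-Hz \linkS4class{SmO2Trace} (\code{nominalDt = 1})
#' @examples
#' tr <- SmO2Trace(c(0, 2), c(10, 20))
#' traceValues(resampleTo1Hz(tr))   # 10 15 20
#' @rdname resampleTo1Hz
#' @export
setMethod("resampleTo1Hz", "SmO2Trace",
function(x, maxGapS = 4, method = c("linear", "constant")) {
    method <- match.arg(method)
    if (length(x@times) < 2L)
        stop("at least 2 samples are required for resampling")
    gaps <- diff(x@times)
    if (any(gaps > maxGapS)) {
        i <- which(gaps > maxGapS)[1]
        stop(sprintf(
            "gap of %g s between t = %g and t = %g exceeds maxGapS = %g",
            gaps[i], x@times[i], x@times[i + 1], maxGapS))
    }
    grid <- seq(ceiling(x@times[1]), floor(x@times[length(x@times)]))
    vals <- stats::approx(x@times, x@values, xout = grid,
                          method = method, ties = "ordered")$y
    initialize(x, times = as.numeric(grid), values = vals, nominalDt = 1)
})

#' Extract an inclusive integer-second segment from a 1-Hz trace
#'
#' Slices a resampled trace on inclusive bounds: the segment [a, b] carries
#' b - a + 1 samples (a 30-s window holds 31 values, the 45-s terminal
#' region holds 46). The default analysis region of the 3-min all-out test
#' is [135, 180] s, the last 45 s of the effort.
#'
#' @param x a 1-Hz \linkS4class{SmO2Trace} covering [startS, endS]
#' @param startS,endS inclusive bounds in whole seconds
#' @return a \linkS4class{Segment}
#' @examples
#' tr <- resampleTo1Hz(SmO2Trace(seq(-30, 210, 2), rep(30, 121)))
#' length(segmentValues(extractSegment(tr, 135, 180)))   # 46
#' @rdname extractSegment
#' @export
setMethod("extractSegment", "SmO2Trace",
function(x, startS, endS) {
    if (x@nominalDt != 1)
        stop("trace must be resampled to 1 Hz first (see resampleTo1Hz)")
    startS <- as.integer(startS); endS <- as.integer(endS)
    if (endS < startS) stop("'endS' must be >= 'startS'")
    idx <- match(startS:endS, x@times)
    if (anyNA(idx))
        stop(sprintf(
            "requested region [%d, %d] s not covered by trace ([%g, %g] s)",
            startS, endS, min(x@times), max(x@times)))
    new("Segment", startS = startS, endS = endS, values = x@values[idx])
})

#' Values of a Segment
#' @param segment a \linkS4class{Segment}
#' @return numeric vector of length \code{endS - startS + 1}
#' @export
segmentValues <- function(segment) segment@values

#' Default signal-conditioning pipeline
#'
#' Applies the standard conditioning chain: the 5-s trailing moving average
#' (skipped when the trace is already device-smoothed) followed by 1-Hz
#' linear resampling.
#'
#' @param trace an \linkS4class{SmO2Trace}
#' @param maWidth moving-average width in seconds
#' @param maxGapS gap tolerance passed to \code{\link{resampleTo1Hz}}
#' @param forceSmooth re-smooth even if already device-smoothed
#' @return a 1-Hz \linkS4class{SmO2Trace}
#' @export
preprocessTrace <- function(trace, maWidth = 5, maxGapS = 4,
                            forceSmooth = FALSE) {
    resampleTo1Hz(movingAverage(trace, width = maWidth, force = forceSmooth),
                  maxGapS = maxGapS)
}
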
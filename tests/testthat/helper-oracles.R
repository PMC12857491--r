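## Independent brute-force oracles, deliberately coded from the definitions
## rather than sharing any implementation path with the package.

## Windowed mean over the half-open trailing window (t - width, t].
bf_moving_average <- function(times, values, width) {
    out <- numeric(length(times))
    for (i in seq_along(times)) {
        acc <- c()
        for (j in seq_along(times))
            if (times[j] > times[i] - width && times[j] <= times[i])
                acc <- c(acc, values[j])
        out[i] <- sum(acc) / length(acc)
    }
    out
}

## Two-point linear interpolation at a single query time.
bf_interp_one <- function(times, values, tq) {
    if (tq %in% times) return(values[match(tq, times)])
    lo <- max(which(times < tq)); hi <- min(which(times > tq))
    w <- (tq - times[lo]) / (times[hi] - times[lo])
    values[lo] * (1 - w) + values[hi] * w
}

## Exhaustive per-sample stability check for one window of values.
bf_window_stable <- function(values, mode, threshold, metric = "anchored") {
    v0 <- values[1]
    if (metric == "anchored") {
        ok <- TRUE
        for (v in values) {
            dev <- if (mode == "absolute") v - v0 else 100 * (v - v0) / v0
            if (dev < -threshold || dev > threshold) ok <- FALSE
        }
        ok
    } else {
        rng <- max(values) - min(values)
        dev <- if (mode == "absolute") rng else 100 * rng / v0
        dev <= threshold
    }
}

## Exhaustive scan over every candidate window in the region.
bf_detect <- function(region_values, region_start, window_s, mode,
                      threshold, metric = "anchored") {
    n_starts <- length(region_values) - window_s
    for (k in seq_len(n_starts)) {
        win <- region_values[k:(k + window_s)]
        if (bf_window_stable(win, mode, threshold, metric))
            return(list(detected = TRUE,
                        window_start = region_start + k - 1L))
    }
    list(detected = FALSE, window_start = NA_integer_)
}

## Fleiss' kappa from the category-count formula, item by item.
bf_fleiss <- function(ratings) {
    N <- nrow(ratings); n <- ncol(ratings)
    Pi <- numeric(N)
    tot <- c(yes = 0, no = 0)
    for (i in seq_len(N)) {
        ny <- sum(ratings[i, ] == 1); nn <- n - ny
        Pi[i] <- (ny * (ny - 1) + nn * (nn - 1)) / (n * (n - 1))
        tot["yes"] <- tot["yes"] + ny; tot["no"] <- tot["no"] + nn
    }
    p <- tot / (N * n)
    Pe <- p[["yes"]]^2 + p[["no"]]^2
    if (abs(1 - Pe) < 1e-12) return(NA_real_)
    (mean(Pi) - Pe) / (1 - Pe)
}

## A random valid trace on the 2-s grid over the full 4-min sample, kept
## away from the 0/100 rails so relative criteria and shift/scale
## transformations stay well defined.
random_trace <- function(seed = NULL, level = 30, amp = 20) {
    if (!is.null(seed)) set.seed(seed)
    t <- seq(-30, 210, by = 2)
    v <- pmin(pmax(level + cumsum(rnorm(length(t), 0, amp / 20)), 5), 95)
    SmO2Trace(t, v)
}

## A 1-Hz trace whose [135, 180] region takes prescribed values.
trace_with_region <- function(region_values, fill = region_values[1]) {
    t <- -30:210
    v <- rep(fill, length(t))
    v[match(135:180, t)] <- region_values
    SmO2Trace(t, v, nominalDt = 1)
}
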
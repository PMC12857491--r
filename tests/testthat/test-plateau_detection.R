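crit <- defaultCriteria()

test_that("windowIsStable matches the definition on hand-built windows", {
    # constant window: stable under any criterion, zero deviation
    for (cr in crit) {
        res <- windowIsStable(rep(20, 31), cr)
        expect_true(res$stable)
        expect_equal(res$deviation, 0)
    }
    # linear rise 50 -> 56: +6 a.u. endpoint change breaks A5
    res <- windowIsStable(seq(50, 56, length.out = 31), crit$A5)
    expect_false(res$stable)
    expect_equal(res$deviation, 6)
    # a change of exactly +5 sits on the inclusive bound: still stable
    res <- windowIsStable(seq(20, 25, length.out = 31), crit$A5)
    expect_true(res$stable)
    expect_equal(res$deviation, 5)
})

test_that("relative mode scales by the window's first value; v0 = 0 errors", {
    # 40 -> 32 is -8 a.u. = -20%: fails R5 and R10, passes A10
    win <- seq(40, 32, length.out = 31)
    expect_false(windowIsStable(win, crit$R5)$stable)
    expect_false(windowIsStable(win, crit$R10)$stable)
    expect_true(windowIsStable(win, crit$A10)$stable)
    expect_equal(windowIsStable(win, crit$R5)$deviation, -20)

    expect_error(windowIsStable(c(0, rep(1, 30)), crit$R5), "first value is 0")
})

test_that("window length must be windowS + 1", {
    expect_error(windowIsStable(rep(20, 30), crit$A5), "31 values")
})

test_that("stability decisions equal the exhaustive per-sample check", {
    set.seed(101)
    for (i in 1:100) {
        win <- runif(31, 10, 60)
        cr <- sample(crit, 1)[[1]]
        expect_identical(windowIsStable(win, cr)$stable,
                         bf_window_stable(win, cr@mode, cr@threshold),
                         info = sprintf("case %d (%s)", i, cr@id))
    }
    # and for the range metric
    rng <- defaultCriteria(metric = "range")
    for (i in 1:50) {
        win <- runif(31, 10, 60)
        cr <- sample(rng, 1)[[1]]
        expect_identical(windowIsStable(win, cr)$stable,
                         bf_window_stable(win, cr@mode, cr@threshold, "range"))
    }
})

test_that("detectPlateau scans 135..150 and the earliest stable window wins", {
    flat <- trace_with_region(rep(30, 46))
    res <- detectPlateau(flat, crit$A5)
    expect_true(isDetected(res))
    expect_equal(windowStart(res), 135L)

    # decline of 1 a.u./s: every 30-s window changes by 30 a.u.
    ramp <- trace_with_region(seq(80, 35, by = -1))
    res <- detectPlateau(ramp, crit$A5)
    expect_false(isDetected(res))
    expect_true(is.na(windowStart(res)))

    # steep decline (5.5 a.u./s) until 150 s then exactly constant: the
    # window anchored at 149 still sees -5.5 a.u., so only [150, 180] fits
    vals <- c(10 + 5.5 * (150 - (135:150)), rep(10, 30))
    res <- detectPlateau(trace_with_region(vals), crit$A5)
    expect_true(isDetected(res))
    expect_equal(windowStart(res), 150L)
})

test_that("detectPlateau agrees with the brute-force scan on random traces", {
    set.seed(202)
    for (i in 1:100) {
        tr <- resampleTo1Hz(random_trace(level = runif(1, 20, 60)))
        region <- segmentValues(extractSegment(tr, 135, 180))
        cr <- sample(crit, 1)[[1]]
        got <- detectPlateau(tr, cr)
        want <- bf_detect(region, 135L, 30L, cr@mode, cr@threshold)
        expect_identical(isDetected(got), want$detected)
        expect_identical(windowStart(got), want$window_start)
    }
})

test_that("threshold monotonicity: every A5/R5 positive is A10/R10 positive", {
    set.seed(303)
    for (i in 1:60) {
        tr <- resampleTo1Hz(random_trace(level = runif(1, 20, 60)))
        res <- classifyAllCriteria(tr)
        if (isDetected(res$A5)) expect_true(isDetected(res$A10))
        if (isDetected(res$R5)) expect_true(isDetected(res$R10))
    }
})

test_that("absolute decisions ignore offsets; relative decisions ignore scale", {
    set.seed(404)
    for (i in 1:30) {
        tr <- resampleTo1Hz(random_trace(level = runif(1, 30, 50)))
        tr <- initialize(tr, values = pmin(pmax(traceValues(tr), 20), 70))
        up <- initialize(tr, values = traceValues(tr) + 10)
        dn <- initialize(tr, values = traceValues(tr) - 10)
        expect_identical(isDetected(detectPlateau(tr, crit$A5)),
                         isDetected(detectPlateau(up, crit$A5)))
        expect_identical(isDetected(detectPlateau(tr, crit$A10)),
                         isDetected(detectPlateau(dn, crit$A10)))
        scaled <- initialize(tr, values = traceValues(tr) * 1.2)
        expect_identical(isDetected(detectPlateau(tr, crit$R5)),
                         isDetected(detectPlateau(scaled, crit$R5)))
        expect_identical(isDetected(detectPlateau(tr, crit$R10)),
                         isDetected(detectPlateau(scaled, crit$R10)))
    }
})

test_that("metric nesting: range-stable implies anchored-stable at T, and anchored implies range at 2T", {
    set.seed(505)
    anchored5 <- crit$A5
    range5 <- defaultCriteria(metric = "range")$A5
    range10 <- defaultCriteria(metric = "range")$A10
    for (i in 1:80) {
        # spreads straddling the thresholds so both outcomes occur
        win <- 40 + runif(31, -1, 1) * runif(1, 1, 8)
        r5 <- windowIsStable(win, range5)$stable
        a5 <- windowIsStable(win, anchored5)$stable
        r10 <- windowIsStable(win, range10)$stable
        expect_true(!r5 || a5)    # range at T nests inside anchored at T
        expect_true(!a5 || r10)   # anchored at T nests inside range at 2T
    }
})

test_that("classifyAllCriteria reproduces the worked arithmetic cases", {
    # anchored change of -8 a.u. in every 30-s window from a ~40 a.u. level:
    # A5 F, A10 T, R5 F (about -20%), R10 F
    vals <- 40 - (8 / 30) * (0:45)
    res <- classifyAllCriteria(trace_with_region(vals))
    expect_false(isDetected(res$A5))
    expect_true(isDetected(res$A10))
    expect_false(isDetected(res$R5))
    expect_false(isDetected(res$R10))

    # low plateau near 20 a.u. with -1.5 a.u. change per window: a tiny
    # absolute change is ~7.5% of the plateau level, so only R5 fails
    vals <- 20 - (1.5 / 30) * (0:45)
    res <- classifyAllCriteria(trace_with_region(vals))
    expect_true(isDetected(res$A5))
    expect_true(isDetected(res$A10))
    expect_false(isDetected(res$R5))
    expect_true(isDetected(res$R10))
})

test_that("a region pinned at the device rail is classified but flagged", {
    flat0 <- trace_with_region(rep(0, 46))
    expect_warning(res <- detectPlateau(flat0, crit$A5), "rail")
    expect_true(isDetected(res))
})
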
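test_that("loadTrial parses a minimal CSV and infers the sampling interval", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("time_s,smo2_pct", "0,60.0", "2,60.0"), f)
    tr <- loadTrial(f)
    expect_s4_class(tr, "SmO2Trace")
    expect_length(traceValues(tr), 2)
    expect_equal(nominalDt(tr), 2)
})

test_that("loadTrial rejects degenerate and malformed inputs distinctly", {
    empty <- withr::local_tempfile(fileext = ".csv")
    writeLines("time_s,smo2_pct", empty)
    expect_error(loadTrial(empty), "no samples")

    expect_error(loadTrial(tempfile("nope")), "not found")

    nonmono <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("time_s,smo2_pct", "0,60", "2,61", "1,62"), nonmono)
    expect_error(loadTrial(nonmono), "non-monotonic")

    nonnum <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("time_s,smo2_pct", "0,60", "2,abc"), nonnum)
    expect_error(loadTrial(nonnum), "non-numeric")

    oor <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("time_s,smo2_pct", "0,60", "2,101"), oor)
    expect_error(loadTrial(oor), "outside")
    clipped <- suppressWarnings(loadTrial(oor, clip = TRUE))
    expect_equal(max(traceValues(clipped)), 100)
})

test_that("alternative column layouts are absorbed by the mapping config", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("elapsed,hr,SmO2", "0,120,55", "2,121,54"), f)
    tr <- loadTrial(f, timeCol = "elapsed", valueCol = "SmO2")
    expect_equal(traceValues(tr), c(55, 54))
    tr2 <- loadTrial(f, timeCol = 1, valueCol = 3)
    expect_equal(traceValues(tr2), c(55, 54))
})

test_that("write-then-load round-trips random valid traces exactly", {
    for (seed in 1:5) {
        tr <- random_trace(seed)
        f <- withr::local_tempfile(fileext = ".csv")
        expect_equal(readLines(writeTrial(tr, f))[1], "time_s,smo2_pct")
        back <- loadTrial(f, subject = subjectId(tr))
        expect_identical(traceTimes(back), traceTimes(tr))
        expect_identical(traceValues(back), traceValues(tr))
    }
})

test_that("writeTrial enforces trace invariants before writing", {
    bad <- SmO2Trace(c(0, 2), c(60, 60))
    bad@values[2] <- 101  # bypass the constructor
    expect_error(writeTrial(bad, withr::local_tempfile()), "0, 100")
})

test_that("loadCohort returns one trace per row with correct grouping", {
    dir <- withr::local_tempdir()
    rows <- expand.grid(muscle = c("vastus_lateralis", "triceps_brachii"),
                        condition = c("normoxia", "hypoxia"),
                        stringsAsFactors = FALSE)
    mf <- data.frame(path = sprintf("t%d.csv", 1:4), subject_id = "S01",
                     muscle = rows$muscle, condition = rows$condition)
    for (p in mf$path)
        writeTrial(random_trace(match(p, mf$path)), file.path(dir, p))
    writeManifest(mf, file.path(dir, "manifest.csv"))

    cohort <- loadCohort(file.path(dir, "manifest.csv"))
    expect_equal(length(cohort), 4)
    groups <- cohortGroups(cohort)
    expect_length(groups, 4)
    expect_true(all(lengths(groups) == 1))
    expect_equal(sum(lengths(groups)), nrow(mf))
})

test_that("manifest validation rejects duplicates and missing files", {
    dir <- withr::local_tempdir()
    writeTrial(random_trace(1), file.path(dir, "a.csv"))
    dup <- data.frame(path = c("a.csv", "a.csv"), subject_id = "S01",
                      muscle = "vastus_lateralis", condition = "normoxia")
    expect_error(readManifest(dup, baseDir = dir), "duplicate")

    ghost <- data.frame(path = "missing.csv", subject_id = "S01",
                        muscle = "vastus_lateralis", condition = "normoxia")
    expect_error(readManifest(ghost, baseDir = dir), "missing")
})

test_that("strict mode aborts on a bad file; lenient mode skips it", {
    dir <- withr::local_tempdir()
    writeTrial(random_trace(1), file.path(dir, "good.csv"))
    writeLines("time_s,smo2_pct", file.path(dir, "bad.csv"))
    mf <- data.frame(path = c("good.csv", "bad.csv"),
                     subject_id = c("S01", "S02"),
                     muscle = "vastus_lateralis", condition = "normoxia")
    writeManifest(mf, file.path(dir, "manifest.csv"))
    expect_error(loadCohort(file.path(dir, "manifest.csv")), "bad.csv")
    expect_warning(
        cohort <- loadCohort(file.path(dir, "manifest.csv"), strict = FALSE),
        "bad.csv")
    expect_equal(length(cohort), 1)
})

test_that("values at the device rails load with a warning, not an error", {
    f <- withr::local_tempfile(fileext = ".csv")
    writeLines(c("time_s,smo2_pct", "0,0", "2,50"), f)
    expect_warning(tr <- loadTrial(f), "floor/ceiling")
    expect_equal(traceValues(tr)[1], 0)
})
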
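make_det <- function(n_per_group = 10, positives = 7) {
    groups <- expand.grid(muscle = c("vastus_lateralis", "triceps_brachii"),
                          condition = c("normoxia", "hypoxia"),
                          stringsAsFactors = FALSE)
    meta <- groups[rep(seq_len(nrow(groups)), each = n_per_group), ]
    det <- matrix(FALSE, nrow(meta), 2, dimnames = list(NULL, c("A5", "A10")))
    for (g in seq_len(nrow(groups))) {
        idx <- (g - 1) * n_per_group + seq_len(positives)
        det[idx, ] <- TRUE
    }
    list(det = det, meta = meta)
}

test_that("summarizeCohort counts per group per criterion by construction", {
    x <- make_det(10, 7)
    summ <- summarizeCohort(x$det, meta = x$meta)
    expect_equal(nrow(summ), 8)  # 2 criteria x 4 groups
    expect_true(all(summ$n_total == 10))
    expect_true(all(summ$n_plateau == 7))
    expect_equal(unique(summ$pct_plateau), 70)
})

test_that("summarizeCohort handles empty input and keeps full precision", {
    empty <- summarizeCohort(matrix(FALSE, 0, 2,
                                    dimnames = list(NULL, c("A5", "A10"))))
    expect_equal(nrow(empty), 0)

    meta <- data.frame(muscle = rep("vastus_lateralis", 30),
                       condition = rep("normoxia", 30))
    det <- matrix(c(rep(TRUE, 29), FALSE), ncol = 1,
                  dimnames = list(NULL, "A5"))
    summ <- summarizeCohort(det, meta = meta)
    expect_equal(summ$n_plateau, 29)
    expect_equal(summ$pct_plateau, 100 * 29 / 30)  # prints as 96.66
})

test_that("group positives sum to the cohort-wide positive count", {
    set.seed(21)
    meta <- data.frame(
        muscle = sample(c("vastus_lateralis", "triceps_brachii"), 40, TRUE),
        condition = sample(c("normoxia", "hypoxia"), 40, TRUE))
    det <- matrix(rbinom(40, 1, 0.6) == 1, ncol = 1,
                  dimnames = list(NULL, "A5"))
    summ <- summarizeCohort(det, meta = meta)
    expect_equal(sum(summ$n_plateau), sum(det))
    expect_equal(sum(summ$n_total), nrow(det))
})

test_that("comparison matrix is symmetric with 100 on the diagonal", {
    methods <- list(A5 = c(TRUE, TRUE, FALSE), VE = c(TRUE, TRUE, FALSE))
    cm <- buildComparisonMatrix(methods)
    expect_equal(cm$agreement["A5", "VE"], 100)
    expect_equal(diag(cm$agreement), c(A5 = 100, VE = 100))
    expect_identical(cm$agreement, t(cm$agreement))
})

test_that("pairwise agreement matches brute-force comparison on a synthetic grid", {
    set.seed(22)
    methods <- replicate(4, rbinom(8, 1, 0.5) == 1, simplify = FALSE)
    names(methods) <- c("A5", "A10", "VE", "VNE")
    cm <- buildComparisonMatrix(methods)
    for (i in names(methods)) for (j in names(methods)) {
        matches <- sum(methods[[i]] == methods[[j]])
        expect_equal(cm$agreement[i, j], 100 * matches / 8)
    }
    expect_error(buildComparisonMatrix(list(a = TRUE, b = c(TRUE, FALSE))),
                 "misaligned")
})

test_that("per-group agreement splits on muscle and condition", {
    meta <- data.frame(muscle = rep(c("vastus_lateralis", "triceps_brachii"),
                                    each = 4),
                       condition = "normoxia")
    methods <- list(A5 = rep(TRUE, 8),
                    VE = c(rep(TRUE, 4), rep(FALSE, 4)))
    cm <- buildComparisonMatrix(methods, meta = meta)
    vl <- subset(cm$byGroup, muscle == "vastus_lateralis")
    tb <- subset(cm$byGroup, muscle == "triceps_brachii")
    expect_equal(vl$agreement_pct, 100)
    expect_equal(tb$agreement_pct, 0)
})

test_that("meanSdKinetics reproduces closed forms and the independent oracle", {
    mk <- function(v) resampleTo1Hz(SmO2Trace(seq(-30, 210, 2),
                                              rep(v, 121)))
    same <- meanSdKinetics(list(mk(42), mk(42), mk(42)))
    expect_true(all(same$sd == 0))
    expect_true(all(same$mean == 42))

    two <- meanSdKinetics(list(mk(10), mk(20)))
    expect_true(all(two$mean == 15))
    expect_equal(unique(two$sd), sqrt(50), tolerance = 1e-12)  # ~7.071

    set.seed(23)
    traces <- lapply(1:5, function(i) resampleTo1Hz(random_trace()))
    got <- meanSdKinetics(traces)
    m <- sapply(traces, traceValues)
    expect_equal(got$mean, rowMeans(m))
    expect_equal(got$sd, apply(m, 1, function(r)
        sqrt(sum((r - mean(r))^2) / (length(r) - 1))))
})

test_that("meanSdKinetics guards its preconditions", {
    expect_error(meanSdKinetics(list()), "empty")
    a <- resampleTo1Hz(SmO2Trace(c(0, 2, 4), c(1, 2, 3)))
    b <- resampleTo1Hz(SmO2Trace(c(0, 2, 6), c(1, 2, 3)))
    expect_error(meanSdKinetics(list(a, b)), "identical time grid")
    expect_message(one <- meanSdKinetics(list(a)), "undefined")
    expect_true(all(is.na(one$sd)))
})
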
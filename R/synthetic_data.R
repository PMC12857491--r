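#' @include AllClasses.R plateau_detection.R signal_io.R
NULL

## Noise-free backbone of the synthetic SmO2 kinetics:
## baseline before onset; mono-exponential desaturation toward the plateau
## during the effort, plus an optional linear drift switched on at 135 s
## (so a single parameter flips plateau vs non-plateau without touching the
## early kinetics); exponential reoxygenation toward baseline after 180 s.
.backbone <- function(t, p) {
    v <- numeric(length(t))
    pre <- t < p@onsetS
    eff <- t >= p@onsetS & t <= 180
    post <- t > 180
    v[pre] <- p@baseline
    v[eff] <- p@plateauLevel +
        (p@baseline - p@plateauLevel) * exp(-(t[eff] - p@onsetS) / p@tauDrop) +
        p@driftSlope * pmax(0, t[eff] - 135)
    v180 <- p@plateauLevel +
        (p@baseline - p@plateauLevel) * exp(-(180 - p@onsetS) / p@tauDrop) +
        p@driftSlope * 45
    v[post] <- p@baseline + (v180 - p@baseline) * exp(-(t[post] - 180) / p@reoxyTau)
    pmin(pmax(v, 0), 100)
}

.with_seed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv())) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()))
    }
    set.seed(seed)
    force(expr)
}

#' Generate one ground-truth-labelled synthetic trial
#'
#' Samples the synthetic SmO2 backbone every \code{sampleDt} seconds over the
#' 4-min window [-30, 210] s (30 s pre-test, 180 s test, 30 s recovery), adds
#' seeded Gaussian noise and any movement-artifact pulses, and clips to
#' [0, 100]. The ground-truth plateau label is computed by running the
#' labelling criterion (default: A5 anchored) on the noise-free backbone at
#' 1 Hz -- never on the noisy realisation -- so the label is a deterministic
#' function of the parameters.
#'
#' @param params a \linkS4class{SyntheticParams}
#' @param subject,muscle,condition metadata carried on the trace
#' @param labelCriterion criterion used to compute the truth label
#' @return a \linkS4class{LabeledTrial}
#' @examples
#' lt <- generateTrace(syntheticParams(noiseSd = 0, seed = 42))
#' truthLabels(lt)   # TRUE: no drift, decay settled well before 150 s
#' @export
generateTrace <- function(params, subject = "synthetic",
                          muscle = "vastus_lateralis",
                          condition = "normoxia",
                          labelCriterion = defaultCriteria()$A5) {
    validObject(params)
    t <- seq(-30, 210, by = params@sampleDt)
    clean <- .backbone(t, params)
    noisy <- .with_seed(params@seed, clean + stats::rnorm(length(t), 0, params@noiseSd))
    if (nrow(params@artifacts))
        for (k in seq_len(nrow(params@artifacts))) {
            a <- params@artifacts[k, ]
            hit <- t >= a$time & t <= a$time + a$duration
            noisy[hit] <- noisy[hit] + a$magnitude
        }
    noisy <- pmin(pmax(noisy, 0), 100)
    trace <- SmO2Trace(t, noisy, subject = subject, muscle = muscle,
                       condition = condition, nominalDt = params@sampleDt,
                       smoothed = TRUE)
    grid1hz <- seq(-30, 210)
    ref <- SmO2Trace(grid1hz, .backbone(grid1hz, params), subject = subject,
                     muscle = muscle, condition = condition, nominalDt = 1)
    truth <- isDetected(detectPlateau(ref, labelCriterion))
    new("LabeledTrial", trace = trace, truthPlateau = truth, params = params)
}

#' Generate a reproducible labelled synthetic cohort
#'
#' Builds \code{nPerGroup} trials for each muscle-by-condition group with a
#' requested mix of true-plateau trials (zero late drift) and plateau-breaking
#' trials (late drift, default -0.3 a.u./s). The number of true-plateau
#' trials per group is \code{floor(nPerGroup * plateauFraction + 0.5)}.
#' Baselines are drawn uniformly from 60--75 a.u. and plateau levels from
#' 10--22 a.u., the band spanned by the printed group means of 3-min all-out
#' tests in trained athletes. All randomness derives from \code{seed}.
#'
#' @param nPerGroup trials per group (the study design uses 30)
#' @param plateauFraction proportion of true-plateau trials per group
#' @param groups data.frame with columns muscle, condition (default: the
#'   full 2 x 2 design, vastus lateralis / triceps brachii x normoxia /
#'   hypoxia)
#' @param noiseSd Gaussian noise SD in a.u. (default 1)
#' @param driftSlope late drift (a.u./s) given to plateau-breaking trials
#' @param seed integer seed controlling all draws
#' @param dir when given, trial CSVs and a \code{manifest.csv} consumable by
#'   \code{\link{loadCohort}} are written there
#' @param labelCriterion criterion defining the ground-truth label
#' @return list with \code{cohort} (an \linkS4class{SmO2Cohort} carrying
#'   truth labels), \code{labeled} (list of \linkS4class{LabeledTrial}) and
#'   \code{manifest} (data.frame, paths filled in when \code{dir} is given)
#' @examples
#' syn <- generateCohort(nPerGroup = 3, plateauFraction = 1, seed = 7)
#' truthLabels(syn$cohort)
#' @export
generateCohort <- function(nPerGroup = 30, plateauFraction = 0.9,
                           groups = data.frame(
                               muscle = rep(c("vastus_lateralis",
                                              "triceps_brachii"), 2),
                               condition = rep(c("normoxia", "hypoxia"),
                                               each = 2)),
                           noiseSd = 1, driftSlope = -0.3, seed = 1L,
                           dir = NULL, labelCriterion = defaultCriteria()$A5) {
    if (nPerGroup <= 0) stop("'nPerGroup' must be positive")
    if (plateauFraction < 0 || plateauFraction > 1)
        stop("'plateauFraction' must lie in [0, 1]")
    nTrue <- floor(nPerGroup * plateauFraction + 0.5)
    labeled <- list()
    rows <- list()
    .with_seed(as.integer(seed), {
        for (g in seq_len(nrow(groups))) {
            for (i in seq_len(nPerGroup)) {
                isTrue <- i <= nTrue
                p <- syntheticParams(
                    baseline = stats::runif(1, 60, 75),
                    plateauLevel = stats::runif(1, 10, 22),
                    tauDrop = stats::runif(1, 12, 18),
                    driftSlope = if (isTrue) 0 else driftSlope,
                    noiseSd = noiseSd,
                    seed = sample.int(.Machine$integer.max, 1))
                sid <- sprintf("S%02d", i)
                lt <- generateTrace(p, subject = sid,
                                    muscle = groups$muscle[g],
                                    condition = groups$condition[g],
                                    labelCriterion = labelCriterion)
                labeled[[length(labeled) + 1L]] <- lt
                rows[[length(rows) + 1L]] <- data.frame(
                    path = sprintf("trial_%s_%s_%s.csv", sid,
                                   groups$muscle[g], groups$condition[g]),
                    subject_id = sid, muscle = groups$muscle[g],
                    condition = groups$condition[g],
                    truth = lt@truthPlateau, stringsAsFactors = FALSE)
            }
        }
    })
    manifest <- do.call(rbind, rows)
    cohort <- SmO2Cohort(lapply(labeled, function(x) x@trace),
                         truth = manifest$truth)
    if (!is.null(dir)) {
        if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
        for (i in seq_along(labeled))
            writeTrial(labeled[[i]]@trace, file.path(dir, manifest$path[i]))
        writeManifest(manifest, file.path(dir, "manifest.csv"))
    }
    list(cohort = cohort, labeled = labeled, manifest = manifest)
}
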
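#' @include AllClasses.R AllGenerics.R
NULL

#' Fleiss' kappa for a binary rating matrix
#'
#' Chance-corrected agreement for n raters assigning each of N items to one
#' of two categories (plateau yes/no). With n_ij the number of raters who
#' placed item i in category j, per-item agreement is
#' P_i = sum_j n_ij (n_ij - 1) / (n (n - 1)); kappa is
#' (mean(P_i) - P_e) / (1 - P_e), with P_e the sum of squared overall
#' category proportions. When every rating falls in a single category,
#' P_e = 1 and kappa is mathematically indeterminate: the result carries
#' \code{kappa = NA} with band \code{"undefined"} (agreement is perfect, but
#' chance-corrected agreement is not estimable).
#'
#' @param x a \linkS4class{RatingMatrix}
#' @return an \linkS4class{AgreementResult}
#' @examples
#' m <- ratingMatrix(rbind(rep(1, 4), rep(0, 4)))
#' fleissKappa(m)   # kappa = 1, almost perfect
#' @rdname fleissKappa
#' @export
setMethod("fleissKappa", "RatingMatrix",
function(x) {
    r <- x@ratings
    validObject(x)
    N <- nrow(r); n <- ncol(r)
    n_yes <- rowSums(r)
    counts <- cbind(yes = n_yes, no = n - n_yes)
    Pi <- rowSums(counts * (counts - 1)) / (n * (n - 1))
    p <- colSums(counts) / (N * n)
    Pe <- sum(p^2)
    if (abs(1 - Pe) < .Machine$double.eps^0.5) {
        message("all ratings in a single category: kappa undefined")
        return(new("AgreementResult", kappa = NA_real_, band = "undefined",
                   nItems = N, nRaters = n))
    }
    kappa <- (mean(Pi) - Pe) / (1 - Pe)
    new("AgreementResult", kappa = kappa, band = kappaBand(kappa),
        nItems = N, nRaters = n)
})

#' Landis-Koch interpretation band for a kappa value
#'
#' Maps kappa to the conventional labels with right-closed intervals:
#' below 0 "poor"; [0, 0.20] "slight"; (0.20, 0.40] "fair"; (0.40, 0.60]
#' "moderate"; (0.60, 0.80] "substantial"; (0.80, 1] "almost perfect".
#' Boundary values take the lower band's label. NA maps to "undefined".
#'
#' @param kappa numeric in [-1, 1], or NA
#' @return character label
#' @examples
#' kappaBand(0.735)   # "substantial"
#' kappaBand(-0.068)  # "poor"
#' @export
kappaBand <- function(kappa) {
    if (length(kappa) != 1L) return(vapply(kappa, kappaBand, character(1)))
    if (is.na(kappa)) return("undefined")
    if (kappa < -1 || kappa > 1)
        stop("kappa must lie within [-1, 1], got ", kappa)
    if (kappa < 0) "poor"
    else if (kappa <= 0.20) "slight"
    else if (kappa <= 0.40) "fair"
    else if (kappa <= 0.60) "moderate"
    else if (kappa <= 0.80) "substantial"
    else "almost perfect"
}

#' Majority-vote consensus over raters
#'
#' An item is plateau-positive iff at least \code{minAgree} raters rated it
#' positive. With the study's panel of four raters and the default
#' \code{minAgree = 3}, a 2-2 split is negative.
#'
#' @param x a \linkS4class{RatingMatrix}
#' @param minAgree minimum number of positive ratings (default 3)
#' @return named logical vector, one entry per item
#' @examples
#' m <- ratingMatrix(rbind(c(1, 1, 1, 0), c(1, 1, 0, 0)))
#' consensusVote(m)   # TRUE FALSE
#' @rdname consensusVote
#' @export
setMethod("consensusVote", "RatingMatrix",
function(x, minAgree = 3L) {
    if (minAgree > ncol(x@ratings))
        stop("'minAgree' (", minAgree, ") exceeds the number of raters (",
             ncol(x@ratings), ")")
    out <- rowSums(x@ratings) >= minAgree
    names(out) <- rownames(x@ratings)
    out
})

#' Percent agreement between two binary determination vectors
#'
#' @param a,b logical vectors of equal length, aligned on the same trials
#' @return percentage of matching items, 100 * matches / length
#' @examples
#' percentAgreement(c(TRUE, TRUE, FALSE), c(TRUE, FALSE, FALSE))  # 66.67
#' @export
percentAgreement <- function(a, b) {
    if (length(a) == 0L) stop("empty input")
    if (length(a) != length(b))
        stop("length mismatch: ", length(a), " vs ", length(b))
    100 * sum(a == b) / length(a)
}

#' Read a ratings CSV into a RatingMatrix
#'
#' Expects one row per trial with a \code{trial_id} column followed by one
#' column per rater holding yes/no or 1/0.
#'
#' @param path CSV file path
#' @param raterClass \code{"expert"} or \code{"non_expert"}
#' @return a \linkS4class{RatingMatrix}
#' @export
readRatings <- function(path, raterClass = "expert") {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!"trial_id" %in% names(df))
        stop("ratings CSV needs a 'trial_id' column")
    m <- as.matrix(df[, setdiff(names(df), "trial_id"), drop = FALSE])
    if (is.character(m)) m <- matrix(as.integer(tolower(m) == "yes"),
                                     nrow = nrow(m), dimnames = dimnames(m))
    rownames(m) <- df$trial_id
    ratingMatrix(m, raterClass = raterClass)
}
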
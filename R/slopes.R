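#' Robust dose-response slope (Huber IRLS)
#'
#' Fits `profile ~ doseAxis` by iteratively reweighted least squares with
#' Huber's T criterion (tuning constant 1.345, MAD residual scale; up to
#' 50 iterations, convergence tolerance 1e-8) and returns the slope.
#' Exact fits (zero residual variance, e.g. perfectly linear or constant
#' profiles) return the ordinary least-squares slope directly. The dose
#' axis is typically the 0-based index of the dose in the ordered grid —
#' a monotone transform of concentration that preserves the slope sign,
#' the only quantity used downstream.
#'
#' @param profile numeric response values (>= 4)
#' @param doseAxis numeric regression axis, same length
#' @return a single numeric slope
#' @export
robustSlope <- function(profile, doseAxis = seq_along(profile) - 1) {
    if (length(profile) < 4L) stop("need at least 4 points")
    if (sd(doseAxis) == 0) stop("zero-variance dose axis")
    ok <- !is.na(profile)
    ols <- lm(profile[ok] ~ doseAxis[ok])
    if (max(abs(stats::residuals(ols))) < 1e-10)
        return(unname(coef(ols)[2]))
    fit <- tryCatch(
        MASS::rlm(profile[ok] ~ doseAxis[ok], psi = MASS::psi.huber,
                  k = 1.345, scale.est = "MAD", maxit = 50L, acc = 1e-8),
        error = function(e) ols)
    unname(coef(fit)[2])
}

## concordance proportion over pairs with defined (nonzero) slope signs
.signConcordance <- function(a, b) {
    sa <- sign(a); sb <- sign(b)
    use <- sa != 0 & sb != 0
    if (!any(use))
        stop("all slope pairs are sign ties; concordance undefined")
    mean(sa[use] == sb[use])
}

## all permutations of 1..n (n small), matrix with one permutation per row
.allPermutations <- function(n) {
    if (n == 1L) return(matrix(1L, 1, 1))
    sub <- .allPermutations(n - 1L)
    do.call(rbind, lapply(seq_len(n), function(i) {
        cbind(i, sub + (sub >= i))
    }))
}

#' Permutation test for cross-dataset slope concordance
#'
#' The observed statistic is the proportion of events whose regression
#' slopes agree in sign between the two datasets (events with a zero
#' slope in either are excluded from the denominator). The null is built
#' by shuffling the event labels of the second slope vector `m` times and
#' recomputing the proportion; the p-value is \eqn{p = (b+1)/(m+1)} with
#' `b` the number of shuffles reaching a proportion at least as large as
#' the observed one, so p can never fall below 1/(m+1). With
#' `exhaustive = TRUE` (only for <= 8 events) all permutations are
#' enumerated instead of sampled.
#'
#' @param slopesA,slopesB paired numeric slope vectors over common events
#' @param m number of shuffles (default 10000)
#' @param seed integer RNG seed
#' @param exhaustive enumerate all permutations instead of sampling
#' @return list: proportion_concordant, b, m, p
#' @export
concordancePermutationTest <- function(slopesA, slopesB, m = 10000L,
                                       seed = 1L, exhaustive = FALSE) {
    stopifnot(length(slopesA) == length(slopesB))
    if (!exhaustive && m < 1L) stop("m must be >= 1")
    obs <- .signConcordance(slopesA, slopesB)
    n <- length(slopesB)
    if (exhaustive) {
        if (n > 8L) stop("exhaustive enumeration limited to 8 events")
        perms <- .allPermutations(n)
        props <- apply(perms, 1, function(ix)
            tryCatch(.signConcordance(slopesA, slopesB[ix]),
                     error = function(e) NA_real_))
        m <- nrow(perms)
        b <- sum(props >= obs, na.rm = TRUE)
    } else {
        b <- .withSeed(seed, {
            sum(vapply(seq_len(m), function(i) {
                p <- tryCatch(.signConcordance(slopesA, sample(slopesB)),
                              error = function(e) NA_real_)
                !is.na(p) && p >= obs
            }, logical(1)))
        })
    }
    list(proportion_concordant = obs, b = as.integer(b), m = as.integer(m),
         p = (b + 1) / (m + 1))
}

#' Eligibility filter for gene-expression profile clustering
#'
#' Retains rows (genes) whose expression is at least `minValue` in at
#' least `minLibraries` libraries and whose fold change relative to the
#' control column reaches `minFold` in at least one treated library.
#'
#' @param mat genes x libraries expression matrix (e.g. FPKM)
#' @param minValue detection floor (default 1)
#' @param minLibraries minimum libraries at or above the floor (default 4)
#' @param minFold minimum treated/control fold change (default 2)
#' @param controlCol index or name of the control library (default 1)
#' @return the retained row subset of `mat`
#' @export
filterExpressionProfiles <- function(mat, minValue = 1, minLibraries = 4L,
                                     minFold = 2, controlCol = 1L) {
    ctrl <- mat[, controlCol]
    treated <- mat[, setdiff(seq_len(ncol(mat)),
                             if (is.character(controlCol))
                                 match(controlCol, colnames(mat))
                             else controlCol), drop = FALSE]
    detected <- rowSums(mat >= minValue) >= minLibraries
    fold <- apply(treated, 1, max) / ifelse(ctrl > 0, ctrl, NA)
    bigFold <- ifelse(is.na(fold), apply(treated, 1, max) > 0, fold >= minFold)
    mat[detected & bigFold, , drop = FALSE]
}
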
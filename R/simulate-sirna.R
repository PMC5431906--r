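#' Simulate an siRNA-screen conjoined-gene count table
#'
#' Draws per-CG control and treatment supporting-read counts from a
#' near-Gaussian null (rounded, truncated at zero) with per-library scale
#' factors so that upper-quartile normalization is non-trivial. Planted
#' effects multiply the affected (treatment, CG) cells by their fold
#' change before library scaling. A configurable number of CGs are
#' unexpressed in controls (all-zero control columns) and expressed only
#' where an effect is planted, emulating events undetectable under
#' control conditions.
#'
#' @param nCg number of control-detected CG events
#' @param nUnexpressed CGs with zero control expression (default 5)
#' @param treatments character vector of siRNA treatment library names
#' @param nControls number of control libraries (default 4, >= 3)
#' @param effects data.frame (treatment, cg_id, fold) of planted shifts,
#'   or NULL; cg_id in `sprintf("CG%03d", i)`, i can exceed nCg to target
#'   unexpressed CGs
#' @param mu,sd mean and sd of the per-CG null expression (defaults 100,
#'   20)
#' @param libFactorRange per-library scale-factor range (default 0.5-2)
#' @param seed integer RNG seed
#' @return list with `counts` (matrix, rows CG ids, columns libraries)
#'   and `isControl` (named logical per column)
#' @export
simulateSirnaCounts <- function(nCg = 50L, nUnexpressed = 5L,
                                treatments = sprintf("siRNA_%02d", 1:10),
                                nControls = 4L, effects = NULL,
                                mu = 100, sd = 20,
                                libFactorRange = c(0.5, 2),
                                seed = 1L) {
    stopifnot(nControls >= 3L)
    .withSeed(seed, {
        libs <- c(sprintf("control_%d", seq_len(nControls)), treatments)
        isControl <- setNames(grepl("^control_", libs), libs)
        nAll <- nCg + nUnexpressed
        ids <- sprintf("CG%03d", seq_len(nAll))
        libFac <- runif(length(libs), libFactorRange[1], libFactorRange[2])
        base <- matrix(rnorm(nAll * length(libs), mu, sd), nAll,
                       dimnames = list(ids, libs))
        base[base < 0] <- 0
        ## unexpressed CGs: zero everywhere unless an effect is planted
        if (nUnexpressed > 0)
            base[(nCg + 1L):nAll, ] <- 0
        if (!is.null(effects)) for (i in seq_len(nrow(effects))) {
            cg <- effects$cg_id[i]; tr <- effects$treatment[i]
            if (!cg %in% ids || !tr %in% libs)
                stop("planted effect references unknown CG or treatment")
            v <- base[cg, tr]
            base[cg, tr] <- if (v > 0) v * effects$fold[i]
                            else mu * effects$fold[i]
        }
        counts <- round(sweep(base, 2L, libFac, `*`))
        list(counts = counts, isControl = isControl)
    })
}
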
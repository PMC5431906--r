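#' Upper-quartile normalize an siRNA-screen count table
#'
#' Divides each library's values by that library's 75th percentile of
#' nonzero counts (linear interpolation between order statistics) and
#' multiplies by the mean of those percentiles across libraries, so the
#' overall scale is preserved and the operation is idempotent. An
#' all-zero library cannot be normalized and raises an error naming it.
#'
#' @param counts matrix, rows = CG ids, columns = libraries
#' @return normalized numeric matrix of the same shape
#' @export
upperQuartileNormalize <- function(counts) {
    uq <- apply(counts, 2, function(x) {
        nz <- x[x > 0]
        if (length(nz) == 0L) NA_real_ else quantile(nz, 0.75, names = FALSE)
    })
    if (anyNA(uq))
        stop("all-zero library: ",
             paste(colnames(counts)[is.na(uq)], collapse = ", "))
    sweep(counts, 2, uq, `/`) * mean(uq)
}

#' Group conjoined genes by control-library detection
#'
#' Partitions CG ids into those detected (nonzero raw count) in at least
#' three control libraries, those detected in no control library, and
#' all others.
#'
#' @param counts raw count matrix (rows = CG ids)
#' @param isControl logical vector flagging control columns (named or
#'   positional)
#' @return list: in_ge3_controls, in_zero_controls, other (character
#'   vectors of CG ids)
#' @export
groupCgByControlDetection <- function(counts, isControl) {
    ctrl <- counts[, isControl, drop = FALSE]
    if (ncol(ctrl) < 3L)
        stop("need at least 3 control libraries")
    nDet <- rowSums(ctrl > 0)
    list(in_ge3_controls = rownames(counts)[nDet >= 3],
         in_zero_controls = rownames(counts)[nDet == 0],
         other = rownames(counts)[nDet > 0 & nDet < 3])
}

#' Apply the control-based expression filter
#'
#' For CGs detected in at least three control libraries, a treatment
#' value is retained only if it exceeds that CG's control mean plus two
#' control standard deviations (sample SD, computed on normalized
#' values). CGs undetected in every control library are assumed
#' unexpressed under control conditions, so any positive treatment value
#' is retained. Values of CGs in neither group are discarded.
#'
#' @param normCounts upper-quartile normalized matrix (see
#'   [upperQuartileNormalize()])
#' @param groups partition from [groupCgByControlDetection()]
#' @param isControl logical vector flagging control columns
#' @return data.frame of retained records: cg_id, treatment, value
#' @export
filterCgExpression <- function(normCounts, groups, isControl) {
    treatCols <- which(!isControl)
    rows <- list()
    for (cg in groups$in_ge3_controls) {
        ctrlVals <- normCounts[cg, isControl]
        thr <- mean(ctrlVals) + 2 * sd(ctrlVals)
        for (j in treatCols) {
            v <- normCounts[cg, j]
            if (v > thr)
                rows[[length(rows) + 1L]] <- data.frame(
                    cg_id = cg, treatment = colnames(normCounts)[j],
                    value = v, stringsAsFactors = FALSE)
        }
    }
    for (cg in groups$in_zero_controls) {
        for (j in treatCols) {
            v <- normCounts[cg, j]
            if (v > 0)
                rows[[length(rows) + 1L]] <- data.frame(
                    cg_id = cg, treatment = colnames(normCounts)[j],
                    value = v, stringsAsFactors = FALSE)
        }
    }
    if (length(rows) == 0L)
        return(data.frame(cg_id = character(), treatment = character(),
                          value = numeric(), stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res <- res[order(res$cg_id, res$treatment), , drop = FALSE]
    rownames(res) <- NULL
    res
}

#' Count retained conjoined genes per siRNA treatment
#'
#' @param records retained records from [filterCgExpression()]
#' @param treatments optional character vector of all treatments so that
#'   treatments with zero retained CGs appear with count 0
#' @return named integer vector: distinct retained CG ids per treatment
#' @export
countCgPerTreatment <- function(records, treatments = NULL) {
    if (is.null(treatments)) treatments <- sort(unique(records$treatment))
    out <- setNames(integer(length(treatments)), treatments)
    for (tr in treatments)
        out[tr] <- length(unique(records$cg_id[records$treatment == tr]))
    out
}
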
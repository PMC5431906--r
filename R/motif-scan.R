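#' Construct a position weight matrix object
#'
#' @param id motif id
#' @param rbp RNA-binding protein name
#' @param family RBP family id
#' @param mat positions x 4 matrix of base probabilities, columns A,C,G,T
#'   (rows must sum to 1 within 1e-6)
#' @param background length-4 base frequencies (default uniform), must
#'   sum to 1
#' @return list of class `"PWM"`
#' @export
pwm <- function(id, rbp, family, mat,
                background = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)) {
    mat <- as.matrix(mat)
    colnames(mat) <- c("A", "C", "G", "T")
    if (any(abs(rowSums(mat) - 1) > 1e-6))
        stop("PWM rows must sum to 1")
    if (abs(sum(background) - 1) > 1e-6)
        stop("background must sum to 1")
    structure(list(id = id, rbp = rbp, family = family, mat = mat,
                   background = setNames(as.numeric(background),
                                         c("A", "C", "G", "T"))),
              class = "PWM")
}

#' @export
print.PWM <- function(x, ...) {
    cat("PWM", x$id, "(", x$rbp, ", family", x$family, "):",
        nrow(x$mat), "positions\n")
    invisible(x)
}

## consensus (most probable base per position), DNA alphabet
.pwmConsensus <- function(p) {
    paste(colnames(p$mat)[apply(p$mat, 1, which.max)], collapse = "")
}

#' Read and write PWM text files
#'
#' Plain-text format: one or more records, each a header line
#' `>ID RBP FAMILY` followed by one line per motif position with four
#' whitespace-separated base probabilities in A C G T order. An optional
#' `#background` line after the header gives four frequencies (uniform
#' if absent).
#'
#' @param path file path
#' @return `readPwmSet`: named list of [pwm()] objects
#' @export
readPwmSet <- function(path) {
    lines <- readLines(path)
    lines <- lines[nzchar(trimws(lines))]
    starts <- grep("^>", lines)
    if (length(starts) == 0L) stop("no PWM records in ", path)
    ends <- c(starts[-1] - 1L, length(lines))
    out <- list()
    for (i in seq_along(starts)) {
        hdr <- strsplit(sub("^>", "", lines[starts[i]]), "\\s+")[[1]]
        body <- lines[(starts[i] + 1L):ends[i]]
        bg <- c(0.25, 0.25, 0.25, 0.25)
        bgLine <- grep("^#background", body)
        if (length(bgLine)) {
            bg <- as.numeric(strsplit(trimws(
                sub("^#background", "", body[bgLine[1]])), "\\s+")[[1]])
            body <- body[-bgLine]
        }
        mat <- do.call(rbind, lapply(body, function(l)
            as.numeric(strsplit(trimws(l), "\\s+")[[1]])))
        out[[hdr[1]]] <- pwm(hdr[1], ifelse(length(hdr) > 1, hdr[2], hdr[1]),
                             ifelse(length(hdr) > 2, hdr[3], hdr[1]),
                             mat, bg)
    }
    out
}

#' @rdname readPwmSet
#' @param pwms named list of [pwm()] objects
#' @export
writePwmSet <- function(pwms, path) {
    con <- file(path, "w")
    on.exit(close(con))
    for (p in pwms) {
        writeLines(paste(">", paste(p$id, p$rbp, p$family), sep = ""), con)
        writeLines(paste("#background",
                         paste(format(p$background, digits = 10),
                               collapse = " ")), con)
        writeLines(apply(p$mat, 1, function(r)
            paste(format(r, digits = 10), collapse = " ")), con)
    }
    invisible(path)
}

#' Scan a sequence with a PWM
#'
#' Scores every window of the sense strand with the log-odds score
#' \eqn{\sum_i \log_2(p_{i,b_i} / bg_{b_i})} and retains windows whose
#' score is at least `thresholdFrac` of the maximum achievable score for
#' the PWM under the same background. T and U are equivalent; windows
#' containing other characters never match. Probabilities of zero are
#' floored at `pseudo` before taking logs.
#'
#' @param sequence a single character string (DNA or RNA alphabet)
#' @param p a [pwm()]
#' @param thresholdFrac fraction of the maximum score (default 0.8)
#' @param pseudo probability floor (default 1e-3)
#' @return integer vector of 1-based match start positions (possibly
#'   empty)
#' @export
scanPwm <- function(sequence, p, thresholdFrac = 0.8, pseudo = 1e-3) {
    s <- .asDNA(sequence)
    w <- nrow(p$mat)
    L <- nchar(s)
    if (L < w) return(integer())
    S <- log2(pmax(p$mat, pseudo) /
              matrix(p$background, w, 4, byrow = TRUE))
    maxScore <- sum(apply(S, 1, max))
    thr <- thresholdFrac * maxScore
    v <- match(strsplit(s, "", fixed = TRUE)[[1]], c("A", "C", "G", "T"))
    nWin <- L - w + 1L
    scores <- numeric(nWin)
    for (i in seq_len(w)) {
        si <- S[i, v[i:(i + nWin - 1L)]]
        scores <- scores + ifelse(is.na(si), -Inf, si)
    }
    as.integer(which(scores >= thr))
}

#' Motif density of a region
#'
#' Number of motif matches divided by region length in bp.
#'
#' @param m match count
#' @param l region length in bp (> 0)
#' @return numeric density
#' @export
motifDensity <- function(m, l) {
    if (any(l <= 0)) stop("region length must be positive")
    m / l
}
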
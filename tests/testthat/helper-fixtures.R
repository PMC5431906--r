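## Shared fixtures and independent oracles. Everything is built in code;
## no fixture files.

## Two tandem plus-strand genes on one chromosome with known coordinates.
## GENEA: 4 exons of 100 bp at 100, 300, 500, 700; GENEB: 3 exons of
## 100 bp at 1500, 1700, 1900. All introns canonical GT..AG.
toyAnnotation <- function() {
    aStarts <- c(100L, 300L, 500L, 700L)
    bStarts <- c(1500L, 1700L, 1900L)
    genes <- data.frame(
        gene_id = c("GENEA", "GENEB"), chrom = "chr1",
        start = c(100L, 1500L), end = c(800L, 2000L), strand = "+",
        stringsAsFactors = FALSE)
    txs <- data.frame(transcript_id = c("GENEA.t1", "GENEB.t1"),
                      gene_id = c("GENEA", "GENEB"),
                      stringsAsFactors = FALSE)
    exons <- rbind(
        data.frame(transcript_id = "GENEA.t1", gene_id = "GENEA",
                   chrom = "chr1", start = aStarts, end = aStarts + 100L,
                   strand = "+", exon_number = 1:4,
                   stringsAsFactors = FALSE),
        data.frame(transcript_id = "GENEB.t1", gene_id = "GENEB",
                   chrom = "chr1", start = bStarts, end = bStarts + 100L,
                   strand = "+", exon_number = 1:3,
                   stringsAsFactors = FALSE))
    GenomeAnnotation(genes, txs, exons)
}

## deterministic genome for toyAnnotation with GT..AG at all annotated
## introns (and hence at any exon-boundary junction between them)
toyGenome <- function(seed = 42L) {
    set.seed(seed)
    chars <- sample(c("A", "C", "G", "T"), 2500, replace = TRUE)
    ann <- toyAnnotation()
    for (t in c("GENEA.t1", "GENEB.t1")) {
        ex <- exonTable(ann)
        ex <- ex[ex$transcript_id == t, ]
        ex <- ex[order(ex$start), ]
        for (i in seq_len(nrow(ex) - 1)) {
            lo <- ex$end[i]; hi <- ex$start[i + 1]
            chars[(lo + 1):(lo + 2)] <- c("G", "T")
            chars[(hi - 1):hi] <- c("A", "G")
        }
    }
    ## the intergenic junction GENEA->GENEB also needs GT after exon A3's
    ## donor and AG before exon B2's acceptor: those coincide with the
    ## annotated intron boundaries above
    Biostrings::DNAStringSet(setNames(paste(chars, collapse = ""), "chr1"))
}

## Monte-Carlo marginal-likelihood Bayes factor oracle under uniform
## priors (independent-psi over shared-psi model)
mcBayesFactor <- function(k1, n1, k2, n2, nmc = 2e5, seed = 7L) {
    set.seed(seed)
    u1 <- runif(nmc); u2 <- runif(nmc); u <- runif(nmc)
    mIndep <- mean(dbinom(k1, n1, u1)) * mean(dbinom(k2, n2, u2))
    mShared <- mean(dbinom(k1, n1, u) * dbinom(k2, n2, u))
    mIndep / mShared
}

## brute-force all-windows PWM scorer, independent of scanPwm internals
brutePwmScan <- function(sequence, p, thresholdFrac = 0.8, pseudo = 1e-3) {
    s <- chartr("uU", "tT", toupper(sequence))
    w <- nrow(p$mat)
    if (nchar(s) < w) return(integer())
    S <- log2(pmax(p$mat, pseudo) / matrix(p$background, w, 4, byrow = TRUE))
    thr <- thresholdFrac * sum(apply(S, 1, max))
    hits <- integer()
    for (start in seq_len(nchar(s) - w + 1)) {
        win <- strsplit(substr(s, start, start + w - 1), "")[[1]]
        idx <- match(win, c("A", "C", "G", "T"))
        if (anyNA(idx)) next
        sc <- sum(S[cbind(seq_len(w), idx)])
        if (sc >= thr) hits <- c(hits, start)
    }
    hits
}

## enumeration oracle for the downstream-sequence-element rule: check
## every substring of length >= 6 directly
bruteDse <- function(sequence) {
    s <- chartr("tT", "uU", toupper(sequence))
    chars <- strsplit(s, "")[[1]]
    L <- length(chars)
    if (L < 6) return(FALSE)
    for (i in 1:(L - 5)) for (j in (i + 5):L) {
        w <- chars[i:j]
        if (!all(w %in% c("U", "G"))) next
        g <- which(w == "G")
        if (length(g) > 3) next
        if (length(g) > 1 && any(diff(g) == 1)) next
        return(TRUE)
    }
    FALSE
}

## simple hard-consensus PWM: probability ~1 on the consensus base
hardConsensusPwm <- function(consensus, id = "M1", rbp = "RBP1",
                             family = "F1") {
    bases <- strsplit(chartr("uU", "tT", toupper(consensus)), "")[[1]]
    m <- matrix(1e-3 / 3, length(bases), 4,
                dimnames = list(NULL, c("A", "C", "G", "T")))
    for (i in seq_along(bases)) m[i, bases[i]] <- 1 - 1e-3
    pwm(id, rbp, family, m)
}

## independent permutation enumerator (iterative, distinct from the
## package's recursive generator)
enumeratePermutations <- function(n) {
    perms <- list(1L)
    for (k in 2:n) {
        perms <- unlist(lapply(perms, function(p) {
            lapply(seq_len(k), function(pos) append(p, k, after = pos - 1))
        }), recursive = FALSE)
    }
    do.call(rbind, perms)
}

## adjusted Rand index between two label vectors (mclust is the
## independent implementation)
ari <- function(a, b) mclust::adjustedRandIndex(a, b)

randomSeq <- function(n, alphabet = c("A", "C", "G", "T")) {
    paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
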
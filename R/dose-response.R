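#' Interpolate missing values in a profile matrix
#'
#' Rows exceeding the missingness rules are dropped (with a message):
#' more than `maxMissing` missing values, or — when `forbidConsecutive`
#' is TRUE — any two adjacent missing values. Remaining gaps are filled
#' by linear interpolation between the nearest observed columns; edge
#' gaps take the nearest observed value.
#'
#' @param mat numeric matrix, rows = events, columns = ordered doses
#' @param maxMissing maximum missing values per retained row (default 2)
#' @param forbidConsecutive drop rows with adjacent missing values
#' @return matrix with the retained, fully interpolated rows
#' @export
interpolateMissing <- function(mat, maxMissing = 2L, forbidConsecutive = TRUE) {
    keep <- logical(nrow(mat))
    for (i in seq_len(nrow(mat))) {
        miss <- which(is.na(mat[i, ]))
        if (length(miss) == ncol(mat)) next           # all missing
        if (length(miss) > maxMissing) next
        if (forbidConsecutive && length(miss) > 1 && any(diff(miss) == 1L))
            next
        keep[i] <- TRUE
    }
    if (sum(!keep))
        message(sum(!keep), " row(s) dropped by missingness rules")
    out <- mat[keep, , drop = FALSE]
    for (i in seq_len(nrow(out))) {
        if (!anyNA(out[i, ])) next
        obs <- which(!is.na(out[i, ]))
        out[i, ] <- approx(obs, out[i, obs], xout = seq_len(ncol(out)),
                           rule = 2)$y
    }
    out
}

## row standardization to zero mean, unit variance
.standardizeRows <- function(mat) {
    sds <- apply(mat, 1, sd)
    if (any(sds == 0))
        stop("zero-variance rows: ",
             paste(head(rownames(mat)[sds == 0], 5), collapse = ", "))
    t(scale(t(mat)))
}

## signed adjacency from row profiles
.signedAdjacency <- function(mat, beta) {
    a <- ((1 + cor(t(mat))) / 2)^beta
    diag(a) <- 0
    a
}

## scale-free topology fit of the connectivity distribution: signed R^2
## of log10 p(k) vs log10 k over nBreaks connectivity bins
.scaleFreeFit <- function(k, nBreaks = 10L) {
    if (max(k) == min(k)) return(0)
    bins <- cut(k, nBreaks)
    dk <- tapply(k, bins, mean)
    pk <- tapply(k, bins, length) / length(k)
    ok <- !is.na(dk) & dk > 0
    if (sum(ok) < 3) return(0)
    fit <- lm(log10(pk[ok]) ~ log10(dk[ok]))
    r2 <- summary(fit)$r.squared
    -sign(coef(fit)[2]) * r2
}

#' Select the soft-threshold exponent for a signed network
#'
#' For each candidate exponent, forms the signed adjacency
#' \eqn{a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta}, computes node
#' connectivity and the scale-free topology model fit R^2 (signed: a fit
#' with a positive log-log slope counts as 0). Returns the smallest
#' candidate whose fit first exceeds `fitTarget` while the fit curve's
#' per-step increase has fallen below 0.01. If no candidate reaches a
#' fit of 0.8, a value above 20 is returned — the smallest candidate
#' above 20 at which the fit curve has plateaued (step change < 0.01),
#' or the largest candidate.
#'
#' @param mat profile matrix (>= 50 rows)
#' @param candidates integer vector of exponents (default 1:30)
#' @param fitTarget R^2 target (default 0.8)
#' @param nBreaks connectivity histogram bins (default 10)
#' @return a single integer exponent, with the per-candidate fit curve in
#'   attribute `"fit"`
#' @export
selectSoftThreshold <- function(mat, candidates = 1:30, fitTarget = 0.8,
                                nBreaks = 10L) {
    if (nrow(mat) < 50L)
        stop("need at least 50 rows for scale-free fit estimation")
    X <- .standardizeRows(mat)
    fits <- vapply(candidates, function(b) {
        a <- .signedAdjacency(X, b)
        .scaleFreeFit(rowSums(a), nBreaks)
    }, numeric(1))
    steps <- c(Inf, diff(fits))
    hit <- which(fits > fitTarget & steps < 0.01)
    beta <- if (length(hit)) {
        candidates[hit[1L]]
    } else if (max(fits) >= 0.8) {
        candidates[which(fits > fitTarget)[1L]]
    } else {
        above <- which(candidates > 20)
        plateau <- above[abs(steps[above]) < 0.01]
        if (length(plateau)) candidates[plateau[1L]]
        else candidates[length(candidates)]
    }
    structure(as.integer(beta), fit = setNames(fits, candidates))
}

#' Eigen-event of a profile cluster
#'
#' First principal component of the row-standardized member profiles,
#' sign-oriented to correlate positively with the member average and
#' scaled to unit variance. It is the cluster's representative
#' dose-response.
#'
#' @param mat member x dose matrix (>= 2 rows)
#' @return numeric profile of length ncol(mat), unit variance
#' @export
eigenEvent <- function(mat) {
    if (nrow(mat) < 2L) stop("need at least 2 members")
    X <- .standardizeRows(mat)
    sv <- svd(X, nu = 0, nv = 1)
    if (sv$d[1] < 1e-12) stop("rank-0 member matrix")
    e <- sv$v[, 1]
    avg <- colMeans(X)
    if (cor(e, avg) < 0) e <- -e
    e / sd(e)
}

## unsigned topological overlap on a (signed) adjacency with zero diagonal
.tomSimilarity <- function(a) {
    L <- a %*% a
    k <- rowSums(a)
    kmin <- outer(k, k, pmin)
    tom <- (L + a) / (kmin + 1 - a)
    diag(tom) <- 1
    tom
}

#' Cluster dose-response profiles with a signed correlation network
#'
#' Builds the signed adjacency at exponent `beta`, converts it to
#' topological-overlap dissimilarity, applies average-linkage
#' hierarchical clustering with a static tree cut (at `cutHeight` times
#' the dendrogram's maximum merge height), discards modules smaller than
#' `minModuleSize`, merges modules whose eigen-event dissimilarity
#' (1 - correlation) is below `mergeHeight`, and finally unassigns
#' members whose Pearson correlation with their module's eigen-event is
#' below `memberMinCor`. Cluster ids are renumbered by decreasing size;
#' 0 denotes unassigned.
#'
#' @param mat events x doses matrix (rownames required)
#' @param beta soft-threshold exponent (see [selectSoftThreshold()])
#' @param minModuleSize smallest retained module (default 25)
#' @param mergeHeight eigen-event dissimilarity below which modules merge
#'   (default 0.2)
#' @param memberMinCor member retention threshold (default 0.75)
#' @param cutHeight static cut as a fraction of the maximum merge height
#'   (default 0.99)
#' @return list of class `"ClusterResult"`: `labels` (named integer, 0 =
#'   unassigned), `eigenEvents` (cluster x dose matrix), `softPower`,
#'   `mergedFrom` (list of pre-merge module ids per final cluster)
#' @export
clusterProfiles <- function(mat, beta, minModuleSize = 25L,
                            mergeHeight = 0.2, memberMinCor = 0.75,
                            cutHeight = 0.99) {
    if (is.null(rownames(mat)))
        rownames(mat) <- sprintf("row_%04d", seq_len(nrow(mat)))
    if (nrow(mat) < minModuleSize) {
        warning("fewer rows than minModuleSize; all rows unassigned")
        return(structure(list(labels = setNames(rep(0L, nrow(mat)),
                                                rownames(mat)),
                              eigenEvents = NULL, softPower = beta,
                              mergedFrom = list()),
                         class = "ClusterResult"))
    }
    X <- .standardizeRows(mat)
    a <- .signedAdjacency(X, beta)
    dissTom <- 1 - .tomSimilarity(a)
    h <- hclust(stats::as.dist(dissTom), method = "average")
    lab <- cutree(h, h = cutHeight * max(h$height))
    ## enforce minimum module size
    sizes <- table(lab)
    lab[lab %in% as.integer(names(sizes)[sizes < minModuleSize])] <- 0L
    mergedFrom <- split(unique(lab[lab != 0]), unique(lab[lab != 0]))
    ## merge modules with close eigen-events
    repeat {
        mods <- sort(unique(lab[lab != 0]))
        if (length(mods) < 2L) break
        eig <- vapply(mods, function(m)
            eigenEvent(mat[lab == m, , drop = FALSE]), numeric(ncol(mat)))
        dmat <- 1 - cor(eig)
        diag(dmat) <- Inf
        if (min(dmat) >= mergeHeight) break
        ij <- which(dmat == min(dmat), arr.ind = TRUE)[1, ]
        keepM <- mods[min(ij)]; dropM <- mods[max(ij)]
        lab[lab == dropM] <- keepM
        mergedFrom[[as.character(keepM)]] <-
            c(mergedFrom[[as.character(keepM)]],
              mergedFrom[[as.character(dropM)]])
        mergedFrom[[as.character(dropM)]] <- NULL
    }
    ## renumber by decreasing size, deterministic tie-break on old id
    mods <- sort(unique(lab[lab != 0]))
    if (length(mods)) {
        sz <- vapply(mods, function(m) sum(lab == m), integer(1))
        newId <- setNames(seq_along(mods), mods[order(-sz, mods)])
        lab[lab != 0] <- unname(newId[as.character(lab[lab != 0])])
        names(mergedFrom) <- unname(newId[names(mergedFrom)])
        mergedFrom <- mergedFrom[order(as.integer(names(mergedFrom)))]
    }
    ## eigen-events and membership filter
    mods <- sort(unique(lab[lab != 0]))
    eigenEvents <- NULL
    if (length(mods)) {
        eigenEvents <- t(vapply(mods, function(m)
            eigenEvent(mat[lab == m, , drop = FALSE]), numeric(ncol(mat))))
        rownames(eigenEvents) <- mods
        colnames(eigenEvents) <- colnames(mat)
        for (m in mods) {
            members <- which(lab == m)
            cors <- apply(mat[members, , drop = FALSE], 1, cor,
                          y = eigenEvents[as.character(m), ])
            lab[members[cors < memberMinCor]] <- 0L
        }
    }
    structure(list(labels = setNames(as.integer(lab), rownames(mat)),
                   eigenEvents = eigenEvents, softPower = beta,
                   mergedFrom = mergedFrom),
              class = "ClusterResult")
}

#' @export
print.ClusterResult <- function(x, ...) {
    n <- length(x$labels)
    mods <- table(x$labels[x$labels != 0])
    cat("ClusterResult:", n, "profiles,", length(mods), "clusters",
        "(soft power", paste0(x$softPower, ")"), "\n")
    if (length(mods))
        cat("  sizes:", paste(sprintf("%s=%d", names(mods), mods),
                              collapse = ", "),
            "| unassigned:", sum(x$labels == 0), "\n")
    invisible(x)
}

#' Event-type enrichment of profile clusters
#'
#' One-tailed hypergeometric test per (cluster, type): the probability of
#' observing at least the cluster's count of a type given the background
#' composition, Benjamini-Hochberg adjusted across all cluster x type
#' tests.
#'
#' @param clusterLabels integer vector of cluster assignments (0 =
#'   unassigned, excluded from clusters but retained in the background)
#' @param eventTypes character vector of event classes, same length
#' @return data.frame: cluster, type, observed, cluster_size, expected,
#'   p, p_adj
#' @export
eventTypeEnrichment <- function(clusterLabels, eventTypes) {
    stopifnot(length(clusterLabels) == length(eventTypes))
    N <- length(eventTypes)
    mods <- sort(unique(clusterLabels[clusterLabels != 0]))
    if (length(mods) == 0L) stop("no non-empty clusters")
    types <- sort(unique(eventTypes))
    rows <- list()
    for (m in mods) {
        inC <- clusterLabels == m
        n <- sum(inC)
        if (n == 0L) stop("empty cluster ", m)
        for (ty in types) {
            K <- sum(eventTypes == ty)
            x <- sum(inC & eventTypes == ty)
            p <- phyper(x - 1, K, N - K, n, lower.tail = FALSE)
            rows[[length(rows) + 1L]] <- data.frame(
                cluster = m, type = ty, observed = x, cluster_size = n,
                expected = n * K / N, p = p, stringsAsFactors = FALSE)
        }
    }
    res <- do.call(rbind, rows)
    res$p_adj <- p.adjust(res$p, method = "BH")
    rownames(res) <- NULL
    res
}
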
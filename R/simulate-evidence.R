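#' Simulate PSI dose-response profiles with known shape labels
#'
#' Generates `nASEvents` event profiles over the configured dose grid:
#' a fraction of monotone-up events (PSI rising linearly by
#' `psiEffectSize` across the grid), monotone-down events (falling), and
#' flat events, each with i.i.d. Gaussian noise of sd `noiseSd` added and
#' the result clipped to [0, 1]. Baselines are drawn so the noiseless
#' curves stay inside [0.1, 0.9].
#'
#' @param config a [simulationConfig()]
#' @param eventTypes optional character vector of AS event classes to
#'   sample types from (default c("SE", "RI", "A3SS", "A5SS"))
#' @return list with `psi` (events x doses noisy matrix), `noiseless`
#'   (same without noise), `labels` (character: up/down/flat), `types`
#'   (event class per row)
#' @export
simulateDoseResponseProfiles <- function(config,
                                         eventTypes = c("SE", "RI",
                                                        "A3SS", "A5SS")) {
    validObject(config)
    k <- length(config@doseGrid)
    if (k < 4L) stop("dose grid must have at least 4 points")
    n <- config@nASEvents
    nUp <- round(n * config@psiShapeProps[1])
    nDown <- round(n * config@psiShapeProps[2])
    nFlat <- n - nUp - nDown
    labels <- c(rep("up", nUp), rep("down", nDown), rep("flat", nFlat))
    if (config@psiEffectSize == 0) labels[] <- "flat"
    .withSeed(config@seed + 1L, {
        eff <- config@psiEffectSize
        ramp <- seq(0, 1, length.out = k)
        rows <- matrix(NA_real_, n, k)
        for (i in seq_len(n)) {
            base <- switch(labels[i],
                up = runif(1, 0.1, max(0.1, 0.9 - eff)),
                down = runif(1, min(0.9, 0.1 + eff), 0.9),
                flat = runif(1, 0.1, 0.9))
            rows[i, ] <- switch(labels[i],
                up = base + eff * ramp,
                down = base - eff * ramp,
                flat = rep(base, k))
        }
        noiseless <- .clip01(rows)
        noisy <- .clip01(noiseless +
            matrix(rnorm(n * k, sd = config@noiseSd), n, k))
        ids <- sprintf("event_%04d", seq_len(n))
        dimnames(noisy) <- dimnames(noiseless) <-
            list(ids, as.character(config@doseGrid))
        types <- sample(eventTypes, n, replace = TRUE)
        list(psi = noisy, noiseless = noiseless,
             labels = setNames(labels, ids), types = setNames(types, ids))
    })
}

#' Simulate inclusion/exclusion junction counts from true PSI values
#'
#' For each event and dose, the junction-read total is drawn
#' n ~ Poisson(`depth`), the inclusion count k ~ Binomial(n, psi) and the
#' exclusion count is n - k, so counts always conserve the drawn total.
#'
#' @param psi events x doses matrix of true inclusion fractions
#' @param depth expected junction reads per event per sample
#' @param seed integer RNG seed
#' @return data.frame: event_id, dose, k_inc, k_exc
#' @export
simulateJunctionCounts <- function(psi, depth, seed = 1L) {
    stopifnot(depth >= 0, all(psi >= 0 & psi <= 1))
    ids <- rownames(psi); doses <- colnames(psi)
    .withSeed(seed, {
        out <- expand.grid(event_id = ids, dose = doses,
                           KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
        p <- psi[cbind(match(out$event_id, ids), match(out$dose, doses))]
        n <- rpois(nrow(out), depth)
        k <- rbinom(nrow(out), n, p)
        out$k_inc <- k
        out$k_exc <- n - k
        out[order(match(out$event_id, ids), match(out$dose, doses)), ,
            drop = FALSE] -> out
        rownames(out) <- NULL
        out
    })
}

#' Simulate dose-dependent read-through junction evidence
#'
#' Plants conjoined-gene (CG) events on `nCg` of the annotation's tandem
#' gene pairs: the CG junction runs from the 3' boundary of the upstream
#' gene's penultimate exon to the 5' boundary of the downstream gene's
#' second exon. Per dose, each planted pair's junction-read total
#' n ~ Poisson(`depth`) is split Binomially by the dose's read-through
#' rate: CG junction reads are taken at the expense of the upstream
#' gene's wild-type terminal junction (read-through steals reads from
#' canonical termination rather than adding depth). All other annotated
#' junctions of every gene receive Poisson(`depth`) background reads, and
#' a per-exon coverage table is emitted in which portions removed by the
#' read-through carry wild-type-only depth.
#'
#' @param sim result of [simulateAnnotation()] (annotation + pairs)
#' @param cgRateCurve per-dose read-through probabilities in [0,1]
#' @param doseGrid dose labels, same length as `cgRateCurve`
#' @param depth expected reads per junction per sample
#' @param nCg number of pairs to plant (default: half the pairs)
#' @param seed integer RNG seed
#' @return list with `junctions` (chrom, strand, donor, acceptor, sample,
#'   count), `coverage` (gene_id, region_start, region_end, sample,
#'   mean_depth), `planted` (upstream, downstream, donor, acceptor)
#' @export
simulateCgReadthrough <- function(sim, cgRateCurve, doseGrid, depth,
                                  nCg = NULL, seed = 1L) {
    stopifnot(all(cgRateCurve >= 0 & cgRateCurve <= 1),
              length(cgRateCurve) == length(doseGrid))
    ann <- sim$annotation
    pairs <- sim$pairs
    if (is.null(nCg)) nCg <- max(1L, nrow(pairs) %/% 2L)
    stopifnot(nCg <= nrow(pairs))
    .withSeed(seed, {
        plantIdx <- sort(sample(nrow(pairs), nCg))
        planted <- list(); jrows <- list(); crows <- list()
        doseLabels <- as.character(doseGrid)
        for (p in seq_len(nrow(pairs))) {
            up <- pairs$upstream[p]; dn <- pairs$downstream[p]
            upEx <- .txExons(ann, .longestTranscript(ann, up))
            dnEx <- .txExons(ann, .longestTranscript(ann, dn))
            chrom <- upEx$chrom[1]
            isPlanted <- p %in% plantIdx
            donor <- upEx$end[nrow(upEx) - 1L]       # penultimate exon 3'
            acceptor <- dnEx$start[2L]               # second exon 5'
            if (isPlanted)
                planted[[length(planted) + 1L]] <- data.frame(
                    upstream = up, downstream = dn, chrom = chrom,
                    donor = donor, acceptor = acceptor,
                    stringsAsFactors = FALSE)
            upJ <- .txJunctions(upEx); dnJ <- .txJunctions(dnEx)
            nUpJ <- nrow(upJ)
            for (d in seq_along(doseLabels)) {
                smp <- doseLabels[d]
                rate <- if (isPlanted) cgRateCurve[d] else 0
                nTot <- rpois(1L, depth)
                nCgReads <- rbinom(1L, nTot, rate)
                nWt <- nTot - nCgReads
                ## upstream gene junctions: terminal junction carries only
                ## wild-type reads, internal junctions full depth
                for (jj in seq_len(nUpJ)) {
                    cnt <- if (jj == nUpJ) nWt else rpois(1L, depth)
                    if (cnt > 0)
                        jrows[[length(jrows) + 1L]] <- data.frame(
                            chrom = chrom, strand = "+", donor = upJ$lo[jj],
                            acceptor = upJ$hi[jj], sample = smp, count = cnt,
                            stringsAsFactors = FALSE)
                }
                for (jj in seq_len(nrow(dnJ))) {
                    cnt <- if (jj == 1L && isPlanted) nWt else rpois(1L, depth)
                    if (cnt > 0)
                        jrows[[length(jrows) + 1L]] <- data.frame(
                            chrom = chrom, strand = "+", donor = dnJ$lo[jj],
                            acceptor = dnJ$hi[jj], sample = smp, count = cnt,
                            stringsAsFactors = FALSE)
                }
                if (nCgReads > 0)
                    jrows[[length(jrows) + 1L]] <- data.frame(
                        chrom = chrom, strand = "+", donor = donor,
                        acceptor = acceptor, sample = smp, count = nCgReads,
                        stringsAsFactors = FALSE)
                ## per-exon coverage: removed portions carry wild-type depth
                covOne <- function(ex, gid, removedIdx) {
                    dep <- rep(nTot, nrow(ex))
                    dep[removedIdx] <- nWt
                    data.frame(gene_id = gid, region_start = ex$start,
                               region_end = ex$end, sample = smp,
                               mean_depth = dep, stringsAsFactors = FALSE)
                }
                crows[[length(crows) + 1L]] <- covOne(
                    upEx, up, if (isPlanted) nrow(upEx) else integer())
                crows[[length(crows) + 1L]] <- covOne(
                    dnEx, dn, if (isPlanted) 1L else integer())
            }
        }
        junctions <- if (length(jrows)) do.call(rbind, jrows) else
            data.frame(chrom = character(), strand = character(),
                       donor = integer(), acceptor = integer(),
                       sample = character(), count = integer(),
                       stringsAsFactors = FALSE)
        rownames(junctions) <- NULL
        coverage <- do.call(rbind, crows)
        rownames(coverage) <- NULL
        plantedDf <- if (length(planted)) do.call(rbind, planted) else
            data.frame(upstream = character(), downstream = character(),
                       chrom = character(), donor = integer(),
                       acceptor = integer(), stringsAsFactors = FALSE)
        list(junctions = junctions, coverage = coverage, planted = plantedDf)
    })
}
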
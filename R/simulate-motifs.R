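#' Plant motif consensus occurrences at a target density
#'
#' Overwrites sequence within each specified region with copies of a
#' motif consensus at non-overlapping uniformly drawn positions so that
#' the region's occurrence density (occurrences / region length)
#' approximates the requested value. Colliding positions are re-drawn up
#' to `retryCap` times, then an error is raised, keeping the density
#' arithmetic exact. Regions with density 0 are left untouched, as are
#' all non-target regions. A requested occupancy (density x motif
#' length) above 1 is infeasible and raises an error.
#'
#' @param genome `Biostrings::DNAStringSet` or named character vector
#' @param spec data.frame with columns chrom, start, end (0-based
#'   half-open), consensus (RNA or DNA alphabet), density (occurrences
#'   per bp)
#' @param seed integer RNG seed
#' @param retryCap maximum redraw attempts per region (default 100)
#' @return modified genome, same class as the input
#' @export
plantMotifs <- function(genome, spec, seed = 1L, retryCap = 100L) {
    isDSS <- methods::is(genome, "DNAStringSet")
    seqs <- if (isDSS) setNames(as.character(genome), names(genome))
            else genome
    .withSeed(seed, {
        for (i in seq_len(nrow(spec))) {
            d <- spec$density[i]
            if (d == 0) next
            cons <- .asDNA(spec$consensus[i])
            w <- nchar(cons)
            len <- spec$end[i] - spec$start[i]
            if (w >= len)
                stop("motif consensus longer than target region")
            if (d * w > 1)
                stop("requested density ", d, " implies occupancy > 1")
            target <- round(d * len)
            if (target == 0L) next
            maxStart <- len - w  # 0-based offsets 0..maxStart
            pos <- sort(sample(0:maxStart, target))
            tries <- 0L
            while (any(diff(pos) < w)) {
                bad <- which(c(FALSE, diff(pos) < w))
                pos[bad] <- sample(0:maxStart, length(bad))
                pos <- sort(pos)
                tries <- tries + 1L
                if (tries > retryCap)
                    stop("could not place ", target,
                         " non-overlapping motif copies in region ", i)
            }
            s <- seqs[[spec$chrom[i]]]
            for (p in pos) {
                at <- spec$start[i] + p  # 0-based genomic
                substr(s, at + 1L, at + w) <- cons
            }
            seqs[[spec$chrom[i]]] <- s
        }
        if (isDSS) Biostrings::DNAStringSet(seqs) else seqs
    })
}
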
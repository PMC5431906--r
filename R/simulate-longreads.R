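#' Simulate long reads as junction chains
#'
#' Emits reads drawn from annotated transcripts and from planted
#' read-through (CG) isoforms. A transcript read's junction chain is the
#' transcript's full splice-junction list; a CG read's chain is the
#' upstream gene's junctions 5' of the donor, the CG junction itself,
#' and the downstream gene's junctions 3' of the acceptor. Each read
#' carries aligned-proportion and identity attributes drawn uniformly
#' from the given ranges. With `jitterBp = 0` read junctions match the
#' annotation exactly; with `jitterBp > 0` every junction coordinate is
#' offset by exactly +/- `jitterBp` (sign drawn per junction), so exact
#' matching fails deterministically.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param plantedCg data.frame (upstream, downstream, chrom, donor,
#'   acceptor) of read-through events, or NULL
#' @param nPerTranscript reads per annotated transcript (default 1)
#' @param nPerCg reads per planted CG (default 2)
#' @param jitterBp junction coordinate jitter in bp (default 0)
#' @param alignedProportionRange,identityRange length-2 numeric ranges
#' @param seed integer RNG seed
#' @return data.frame: read_id, chrom, strand, junctions (encoded
#'   `"lo:hi;..."`), aligned_proportion, identity, source
#' @export
simulateLongReads <- function(ann, plantedCg = NULL, nPerTranscript = 1L,
                              nPerCg = 2L, jitterBp = 0L,
                              alignedProportionRange = c(0.92, 1),
                              identityRange = c(0.85, 1),
                              seed = 1L) {
    stopifnot(jitterBp >= 0)
    .withSeed(seed, {
        rows <- list()
        addRead <- function(chrom, strand, j, src) {
            if (jitterBp > 0 && nrow(j) > 0) {
                j$lo <- j$lo + sample(c(-jitterBp, jitterBp), nrow(j),
                                      replace = TRUE)
                j$hi <- j$hi + sample(c(-jitterBp, jitterBp), nrow(j),
                                      replace = TRUE)
            }
            rows[[length(rows) + 1L]] <<- data.frame(
                read_id = sprintf("read_%05d", length(rows) + 1L),
                chrom = chrom, strand = strand,
                junctions = .encodeJunctions(j$lo, j$hi),
                aligned_proportion = runif(1, alignedProportionRange[1],
                                           alignedProportionRange[2]),
                identity = runif(1, identityRange[1], identityRange[2]),
                source = src, stringsAsFactors = FALSE)
        }
        for (t in ann@transcripts$transcript_id) {
            ex <- .txExons(ann, t)
            j <- .txJunctions(ex)
            for (r in seq_len(nPerTranscript))
                addRead(ex$chrom[1], ex$strand[1], j, t)
        }
        if (!is.null(plantedCg)) for (i in seq_len(nrow(plantedCg))) {
            cg <- plantedCg[i, ]
            upJ <- .geneJunctions(ann, cg$upstream)
            dnJ <- .geneJunctions(ann, cg$downstream)
            lo <- min(cg$donor, cg$acceptor)
            hi <- max(cg$donor, cg$acceptor)
            chain <- rbind(upJ[upJ$hi <= lo, , drop = FALSE],
                           data.frame(lo = lo, hi = hi),
                           dnJ[dnJ$lo >= hi, , drop = FALSE])
            chain <- chain[order(chain$lo), , drop = FALSE]
            strand <- ann@genes$strand[ann@genes$gene_id == cg$upstream]
            for (r in seq_len(nPerCg))
                addRead(cg$chrom, strand, chain,
                        paste0("CG:", cg$upstream, "|", cg$downstream))
        }
        res <- do.call(rbind, rows)
        rownames(res) <- NULL
        res
    })
}
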
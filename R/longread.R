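#' Filter long reads on alignment quality attributes
#'
#' Retains reads with aligned proportion >= 0.90 and sequence identity
#' >= 0.80 (both configurable).
#'
#' @param reads data.frame with one row per read: read_id, chrom, strand,
#'   junctions (encoded `"lo:hi;lo:hi"` chains), aligned_proportion,
#'   identity
#' @param minAlignedProportion default 0.90
#' @param minIdentity default 0.80
#' @return the retained subset
#' @export
filterLongReads <- function(reads, minAlignedProportion = 0.90,
                            minIdentity = 0.80) {
    keep <- reads$aligned_proportion >= minAlignedProportion &
        reads$identity >= minIdentity
    reads[keep, , drop = FALSE]
}

#' Map a long read to genes by exact junction matching
#'
#' A read is considered mapped to a gene if at least `minJunctions` of the
#' read's splice junctions exactly match annotated junctions of that gene
#' (coordinates compared as genomic (lo, hi) intron intervals).
#'
#' @param read one-row data.frame or list with chrom and junctions
#'   (encoded chain, see [filterLongReads()])
#' @param ann a [GenomeAnnotation-class]
#' @param minJunctions minimum exact matches per gene (default 3)
#' @return character vector of gene ids (possibly empty)
#' @export
mapReadToGenes <- function(read, ann, minJunctions = 3L) {
    rj <- .decodeJunctions(read$junctions)
    if (nrow(rj) == 0L) return(character())
    rkeys <- .junctionKey(rj$lo, rj$hi)
    g <- ann@genes[ann@genes$chrom == read$chrom, , drop = FALSE]
    hits <- vapply(g$gene_id, function(gid) {
        gj <- .geneJunctions(ann, gid)
        sum(rkeys %in% .junctionKey(gj$lo, gj$hi))
    }, numeric(1))
    sort(g$gene_id[hits >= minJunctions])
}

#' Discover conjoined-gene candidates from long reads
#'
#' A filtered read mapping to exactly two distinct co-oriented genes on
#' one chromosome — neither encapsulated in the other — yields one CG
#' candidate carrying the inter-gene junction (the read junction lying
#' between the two gene spans).
#'
#' @param reads filtered long-read data.frame (see [filterLongReads()])
#' @param ann a [GenomeAnnotation-class]
#' @param minJunctions per-gene junction-match requirement (default 3)
#' @return data.frame: read_id, upstream, downstream, donor, acceptor
#' @export
detectCgLong <- function(reads, ann, minJunctions = 3L) {
    out <- list()
    g <- ann@genes
    for (i in seq_len(nrow(reads))) {
        rd <- reads[i, ]
        genes <- mapReadToGenes(rd, ann, minJunctions)
        if (length(genes) != 2L) next
        a <- g[g$gene_id == genes[1], ]; b <- g[g$gene_id == genes[2], ]
        if (a$strand != b$strand) next
        if (.encapsulated(a, b) || .encapsulated(b, a)) next
        ## order by transcription direction
        if ((a$strand == "+" && a$start > b$start) ||
            (a$strand == "-" && a$start < b$start)) { tmp <- a; a <- b; b <- tmp }
        rj <- .decodeJunctions(rd$junctions)
        ## inter-gene junction: spans the intergenic gap between the two
        ## gene bodies
        gapLo <- min(a$end, b$end); gapHi <- max(a$start, b$start)
        between <- rj$lo <= gapLo & rj$hi >= gapHi
        if (!any(between)) next
        jn <- rj[which(between)[1L], ]
        donor <- if (a$strand == "-") jn$hi else jn$lo
        acceptor <- if (a$strand == "-") jn$lo else jn$hi
        out[[length(out) + 1L]] <- data.frame(
            read_id = rd$read_id, upstream = a$gene_id,
            downstream = b$gene_id, donor = donor, acceptor = acceptor,
            stringsAsFactors = FALSE)
    }
    if (length(out) == 0L)
        return(data.frame(read_id = character(), upstream = character(),
                          downstream = character(), donor = integer(),
                          acceptor = integer(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Count long reads validating a conjoined-gene call
#'
#' A read supports a CG if one of its splice junctions equals the CG's
#' (donor, acceptor) coordinates exactly; `tolerance` (default 0) allows a
#' +/- bp window but the strict exact-match default is the validation
#' criterion.
#'
#' @param cg list with chrom, strand, donor, acceptor
#' @param reads filtered long-read data.frame
#' @param tolerance allowed per-coordinate offset in bp (default 0)
#' @return integer support count
#' @export
validateCg <- function(cg, reads, tolerance = 0L) {
    lo <- min(cg$donor, cg$acceptor); hi <- max(cg$donor, cg$acceptor)
    n <- 0L
    for (i in seq_len(nrow(reads))) {
        if (reads$chrom[i] != cg$chrom) next
        rj <- .decodeJunctions(reads$junctions[i])
        if (any(abs(rj$lo - lo) <= tolerance & abs(rj$hi - hi) <= tolerance))
            n <- n + 1L
    }
    n
}
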
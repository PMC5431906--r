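#' Consecutive gene pairs along each chromosome
#'
#' Orders genes by genomic start within each chromosome and returns
#' adjacent pairs. Adjacency is defined over all genes regardless of
#' strand (the background distribution used for genomic-context
#' comparisons); `sameStrandOnly` then *restricts* the returned pairs to
#' co-oriented ones without re-pairing across an opposite-strand
#' neighbour. Genes encapsulated within another gene's span (e.g. a
#' miRNA inside a host intron) never participate in pairing.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param sameStrandOnly keep only pairs on the same strand
#' @return data.frame with columns upstream, downstream, chrom, strand_up,
#'   strand_dn, distance, overlap
#' @export
consecutiveGenePairs <- function(ann, sameStrandOnly = FALSE) {
    g <- ann@genes
    if (nrow(g) < 2L)
        stop("need at least two genes")
    ## drop encapsulated genes from pairing
    enc <- vapply(seq_len(nrow(g)), function(i) {
        any(vapply(seq_len(nrow(g)), function(j) {
            i != j && .encapsulated(g[i, ], g[j, ])
        }, logical(1)))
    }, logical(1))
    g <- g[!enc, , drop = FALSE]
    out <- list()
    for (chr in unique(g$chrom)) {
        gc <- g[g$chrom == chr, , drop = FALSE]
        gc <- gc[order(gc$start, gc$gene_id), , drop = FALSE]
        if (nrow(gc) < 2L) next
        for (i in seq_len(nrow(gc) - 1L)) {
            up <- gc[i, ]; dn <- gc[i + 1L, ]
            if (sameStrandOnly && up$strand != dn$strand) next
            d <- intergenicDistance(ann, up$gene_id, dn$gene_id)
            out[[length(out) + 1L]] <- data.frame(
                upstream = up$gene_id, downstream = dn$gene_id,
                chrom = chr, strand_up = up$strand, strand_dn = dn$strand,
                distance = d, overlap = attr(d, "overlap"),
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(data.frame(upstream = character(), downstream = character(),
                          chrom = character(), strand_up = character(),
                          strand_dn = character(), distance = integer(),
                          overlap = logical(), stringsAsFactors = FALSE))
    res <- do.call(rbind, out)
    rownames(res) <- NULL
    res
}

#' Intergenic distance between two genes
#'
#' Gap in bp between the end of the gene starting first and the start of
#' the other. Overlapping or abutting genes yield 0; overlap is flagged in
#' the `"overlap"` attribute rather than returned as a negative distance,
#' so distance distributions stay non-negative.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param upstream,downstream gene ids on the same chromosome
#' @return non-negative integer with logical attribute `"overlap"`
#' @export
intergenicDistance <- function(ann, upstream, downstream) {
    g <- ann@genes
    a <- g[g$gene_id == upstream, ]; b <- g[g$gene_id == downstream, ]
    if (nrow(a) != 1L || nrow(b) != 1L)
        stop("unknown gene id")
    if (a$chrom != b$chrom)
        stop("genes '", upstream, "' and '", downstream,
             "' are on different chromosomes")
    if (b$start < a$start) { tmp <- a; a <- b; b <- tmp }
    d <- max(0L, b$start - a$end)
    structure(d, overlap = b$start < a$end)
}

#' Intron lengths of a transcript
#'
#' Gap lengths between consecutive exons in transcription order. A
#' single-exon transcript has no introns.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param transcript_id transcript id
#' @return integer vector (possibly empty)
#' @export
intronLengths <- function(ann, transcript_id) {
    ex <- .txExons(ann, transcript_id)
    if (nrow(ex) == 0L)
        stop("transcript '", transcript_id, "' has no exons")
    j <- .txJunctions(ex)
    if (nrow(j) == 0L) return(integer())
    lens <- j$hi - j$lo
    ## report in transcription order
    if (ex$strand[1] == "-") lens <- rev(lens)
    as.integer(lens)
}

#' Classify a genomic position relative to a gene
#'
#' Assigns exactly one of six labels: `"5'UTR"`, `"CDS"`, `"3'UTR"`,
#' `"non-coding exon"`, `"intron"` or `"intergenic"`. Exonic labels take
#' precedence over `"intron"`. UTR/CDS sub-classification requires coding
#' bounds (`cds_start`/`cds_end`, 0-based half-open, genomic); exonic
#' positions without coding bounds are `"non-coding exon"`. Positions
#' outside the gene span (within any declared flank) are `"intergenic"`.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param gene_id gene id
#' @param position 0-based genomic position
#' @param cds_start,cds_end optional genomic coding-region bounds
#' @return a single label string
#' @export
annotatePositionRegion <- function(ann, gene_id, position,
                                   cds_start = NA, cds_end = NA) {
    g <- ann@genes[ann@genes$gene_id == gene_id, ]
    if (nrow(g) != 1L) stop("unknown gene id '", gene_id, "'")
    if (position < g$start || position >= g$end)
        return("intergenic")
    ex <- ann@exons[ann@exons$gene_id == gene_id, , drop = FALSE]
    inExon <- any(ex$start <= position & position < ex$end)
    if (!inExon) return("intron")
    if (is.na(cds_start) || is.na(cds_end))
        return("non-coding exon")
    if (position >= cds_start && position < cds_end)
        return("CDS")
    ## before CDS in transcription order is the 5' UTR
    before <- position < cds_start
    if (g$strand == "-") before <- position >= cds_end
    if (before) "5'UTR" else "3'UTR"
}

#' Proportion of intervals overlapping any domain
#'
#' Fraction of event intervals overlapping at least one protein-domain
#' interval by >= 1 bp, on a shared genomic coordinate system.
#'
#' @param events data.frame with columns chrom, start, end (0-based
#'   half-open)
#' @param domains data.frame with columns chrom, start, end (e.g.
#'   [domainTable()])
#' @return fraction in [0, 1]
#' @export
domainOverlapProportion <- function(events, domains) {
    if (nrow(events) == 0L)
        stop("empty event list")
    if (nrow(domains) == 0L)
        return(0)
    ev <- GenomicRanges::GRanges(events$chrom,
        IRanges::IRanges(start = events$start + 1L, end = events$end))
    dom <- GenomicRanges::GRanges(domains$chrom,
        IRanges::IRanges(start = domains$start + 1L, end = domains$end))
    hits <- GenomicRanges::countOverlaps(ev, dom, minoverlap = 1L)
    mean(hits > 0)
}
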
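## internal helpers shared across modules

## ordered exons (transcription order) of one transcript
.txExons <- function(ann, transcript_id) {
    ex <- ann@exons[ann@exons$transcript_id == transcript_id, , drop = FALSE]
    ex[order(ex$exon_number), , drop = FALSE]
}

## transcript ids of a gene
.geneTranscripts <- function(ann, gene_id) {
    ann@transcripts$transcript_id[ann@transcripts$gene_id == gene_id]
}

## id of the longest (summed exon length) transcript of a gene;
## deterministic tie-break on transcript id
.longestTranscript <- function(ann, gene_id) {
    txs <- .geneTranscripts(ann, gene_id)
    if (length(txs) == 0L)
        stop("gene '", gene_id, "' has no transcripts")
    len <- vapply(txs, function(t) {
        ex <- .txExons(ann, t)
        sum(ex$end - ex$start)
    }, numeric(1))
    txs[order(-len, txs)][1L]
}

## splice junctions of a transcript as genomic intervals:
## data.frame(lo, hi) with lo = end of the left exon, hi = start of the
## right exon (0-based half-open intron [lo, hi))
.txJunctions <- function(exons) {
    ex <- exons[order(exons$start), , drop = FALSE]
    n <- nrow(ex)
    if (n < 2L)
        return(data.frame(lo = integer(), hi = integer()))
    data.frame(lo = ex$end[-n], hi = ex$start[-1])
}

## unique junctions of a gene across all its transcripts
.geneJunctions <- function(ann, gene_id) {
    txs <- .geneTranscripts(ann, gene_id)
    js <- do.call(rbind, lapply(txs, function(t) .txJunctions(.txExons(ann, t))))
    if (is.null(js) || nrow(js) == 0L)
        return(data.frame(lo = integer(), hi = integer()))
    unique(js)
}

## gene(s) whose span contains a position (0-based) on a chromosome
.genesAtPosition <- function(ann, chrom, pos) {
    g <- ann@genes
    g$gene_id[g$chrom == chrom & g$start <= pos & pos < g$end]
}

## is gene a's span fully contained in gene b's span (either strand)?
.encapsulated <- function(a, b) {
    a$chrom == b$chrom && a$start >= b$start && a$end <= b$end &&
        !(a$start == b$start && a$end == b$end)
}

## junction key for exact matching
.junctionKey <- function(lo, hi) paste(lo, hi, sep = "-")

## serialize/parse a junction chain for TSV interchange ("lo:hi;lo:hi")
.encodeJunctions <- function(lo, hi) paste(paste(lo, hi, sep = ":"), collapse = ";")

.decodeJunctions <- function(s) {
    if (is.na(s) || !nzchar(s))
        return(data.frame(lo = integer(), hi = integer()))
    parts <- strsplit(strsplit(s, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
    data.frame(lo = as.integer(vapply(parts, `[`, "", 1L)),
               hi = as.integer(vapply(parts, `[`, "", 2L)))
}

## clip to [0, 1]
.clip01 <- function(x) pmin(pmax(x, 0), 1)  # keeps matrix dims

## DNA -> RNA sense (T -> U), uppercased
.asRNA <- function(x) chartr("tT", "uU", toupper(x))

## RNA/DNA -> DNA (U -> T), uppercased
.asDNA <- function(x) chartr("uU", "tT", toupper(x))
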
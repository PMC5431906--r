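## run expr with a fixed RNG seed, restoring the caller's RNG state
.withSeed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(suppressWarnings(
            rm(".Random.seed", envir = globalenv())), add = TRUE)
    }
    set.seed(seed)
    force(expr)
}

.sampleRange <- function(r, n = 1L) {
    if (r[1] == r[2]) rep(r[1], n) else sample(seq(r[1], r[2]), n, replace = TRUE)
}

#' Simulate a genome annotation of tandem same-strand gene pairs
#'
#' Lays out `nGenePairs` consecutive pairs of multi-exon, plus-strand
#' genes on one synthetic chromosome, with exon/intron/intergenic lengths
#' drawn from the configured ranges and a large fixed gap between pairs.
#' Each gene carries one transcript spanning all its exons. The returned
#' genome sequence is random with every annotated intron's first two
#' bases forced to GT and last two to AG, so that all annotated splice
#' junctions (and read-through junctions between a pair's genes) are
#' canonical. Deterministic for a fixed config seed.
#'
#' @param config a [simulationConfig()]
#' @param chrom chromosome name (default `"chrS"`)
#' @param interPairGap bp between successive pairs (default 20000)
#' @return list with `annotation` ([GenomeAnnotation-class]), `genome`
#'   (`Biostrings::DNAStringSet`), and `pairs` (data.frame upstream,
#'   downstream)
#' @export
simulateAnnotation <- function(config, chrom = "chrS", interPairGap = 20000L) {
    validObject(config)
    .withSeed(config@seed, {
        cursor <- 1000L
        genes <- list(); txs <- list(); exons <- list(); pairs <- list()
        for (p in seq_len(config@nGenePairs)) {
            ids <- sprintf("G%03d%s", p, c("A", "B"))
            starts <- integer(2)
            for (k in 1:2) {
                gid <- ids[k]
                tid <- paste0(gid, ".t1")
                nEx <- .sampleRange(config@exonsPerGene)
                exLens <- .sampleRange(config@exonLen, nEx)
                inLens <- if (nEx > 1L) .sampleRange(config@intronLen, nEx - 1L)
                          else integer()
                es <- integer(nEx); ee <- integer(nEx)
                pos <- cursor
                for (e in seq_len(nEx)) {
                    es[e] <- pos; ee[e] <- pos + exLens[e]
                    pos <- ee[e] + if (e < nEx) inLens[e] else 0L
                }
                genes[[length(genes) + 1L]] <- data.frame(
                    gene_id = gid, chrom = chrom, start = es[1], end = ee[nEx],
                    strand = "+", stringsAsFactors = FALSE)
                txs[[length(txs) + 1L]] <- data.frame(
                    transcript_id = tid, gene_id = gid,
                    stringsAsFactors = FALSE)
                exons[[length(exons) + 1L]] <- data.frame(
                    transcript_id = tid, gene_id = gid, chrom = chrom,
                    start = es, end = ee, strand = "+",
                    exon_number = seq_len(nEx), stringsAsFactors = FALSE)
                starts[k] <- es[1]
                cursor <- ee[nEx] +
                    if (k == 1L) .sampleRange(config@intergenicLen)
                    else interPairGap
            }
            pairs[[p]] <- data.frame(upstream = ids[1], downstream = ids[2],
                                     stringsAsFactors = FALSE)
        }
        genes <- do.call(rbind, genes)
        txs <- do.call(rbind, txs)
        exons <- do.call(rbind, exons)
        chromLen <- max(genes$end) + 1000L
        seqChars <- sample(c("A", "C", "G", "T"), chromLen, replace = TRUE)
        ## canonical GT..AG at every annotated intron
        for (t in unique(exons$transcript_id)) {
            ex <- exons[exons$transcript_id == t, , drop = FALSE]
            j <- .txJunctions(ex)
            for (i in seq_len(nrow(j))) {
                seqChars[(j$lo[i] + 1L):(j$lo[i] + 2L)] <- c("G", "T")
                seqChars[(j$hi[i] - 1L):j$hi[i]] <- c("A", "G")
            }
        }
        ## and at the intergenic gap of each pair, so a read-through
        ## junction from an internal donor to an internal acceptor still
        ## traverses canonical annotated splice sites only
        genome <- Biostrings::DNAStringSet(
            setNames(paste(seqChars, collapse = ""), chrom))
        ann <- GenomeAnnotation(genes, txs, exons)
        list(annotation = ann, genome = genome,
             pairs = do.call(rbind, pairs))
    })
}
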
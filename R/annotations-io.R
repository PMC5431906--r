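#' Read a GTF gene model into a GenomeAnnotation
#'
#' Accepts GTF with `gene`, `transcript` and `exon` features carrying
#' `gene_id` and `transcript_id` attributes. GTF's 1-based inclusive
#' coordinates are converted to the package's 0-based half-open internal
#' convention (a GTF exon 100-199 becomes the interval \[99, 199), length
#' 100). Records violating the gene model (overlapping exons within a
#' transcript, an exon outside its gene's span) raise an error naming the
#' offending record.
#'
#' @param path GTF file path
#' @return a [GenomeAnnotation-class]
#' @seealso [writeAnnotation()] for the inverse; the round trip is the
#'   identity.
#' @export
loadAnnotation <- function(path) {
    gr <- rtracklayer::import(path, format = "gtf")
    df <- as.data.frame(gr)
    df$seqnames <- as.character(df$seqnames)
    df$strand <- as.character(df$strand)
    ## GTF 1-based inclusive -> 0-based half-open
    df$start0 <- df$start - 1L
    df$end0 <- df$end

    gdf <- df[df$type == "gene", , drop = FALSE]
    genes <- data.frame(gene_id = gdf$gene_id, chrom = gdf$seqnames,
                        start = gdf$start0, end = gdf$end0,
                        strand = gdf$strand, stringsAsFactors = FALSE)
    genes <- genes[order(genes$chrom, genes$start, genes$gene_id), ,
                   drop = FALSE]
    rownames(genes) <- NULL

    tdf <- df[df$type == "transcript", , drop = FALSE]
    transcripts <- data.frame(transcript_id = tdf$transcript_id,
                              gene_id = tdf$gene_id,
                              stringsAsFactors = FALSE)
    transcripts <- transcripts[order(transcripts$gene_id,
                                     transcripts$transcript_id), ,
                               drop = FALSE]
    rownames(transcripts) <- NULL

    edf <- df[df$type == "exon", , drop = FALSE]
    exons <- data.frame(transcript_id = edf$transcript_id,
                        gene_id = edf$gene_id, chrom = edf$seqnames,
                        start = edf$start0, end = edf$end0,
                        strand = edf$strand, stringsAsFactors = FALSE)
    if ("exon_number" %in% names(edf) && !anyNA(edf$exon_number)) {
        exons$exon_number <- as.integer(edf$exon_number)
    } else {
        ## transcription order: ascending start on +, descending on -
        exons$exon_number <- NA_integer_
        for (t in unique(exons$transcript_id)) {
            i <- which(exons$transcript_id == t)
            o <- order(exons$start[i],
                       decreasing = exons$strand[i[1]] == "-")
            exons$exon_number[i[o]] <- seq_along(i)
        }
    }
    exons <- exons[order(exons$transcript_id, exons$exon_number), ,
                   drop = FALSE]
    rownames(exons) <- NULL

    ann <- try(GenomeAnnotation(genes, transcripts, exons), silent = TRUE)
    if (inherits(ann, "try-error"))
        stop("GTF parse error: ", attr(ann, "condition")$message)
    ann
}

#' Write a GenomeAnnotation as GTF
#'
#' Emits `gene`, `transcript` and `exon` records with `gene_id`,
#' `transcript_id` and (for exons) `exon_number` attributes, converting
#' internal 0-based half-open coordinates back to GTF's 1-based inclusive
#' convention.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param path output file path
#' @return `path`, invisibly
#' @export
writeAnnotation <- function(ann, path) {
    g <- ann@genes; tx <- ann@transcripts; ex <- ann@exons
    gix <- match(tx$gene_id, g$gene_id)
    rows <- rbind(
        data.frame(chrom = g$chrom, type = "gene", start = g$start,
                   end = g$end, strand = g$strand, gene_id = g$gene_id,
                   transcript_id = NA_character_,
                   exon_number = NA_integer_, stringsAsFactors = FALSE),
        data.frame(chrom = g$chrom[gix], type = "transcript",
                   start = g$start[gix], end = g$end[gix],
                   strand = g$strand[gix], gene_id = tx$gene_id,
                   transcript_id = tx$transcript_id,
                   exon_number = NA_integer_, stringsAsFactors = FALSE),
        data.frame(chrom = ex$chrom, type = "exon", start = ex$start,
                   end = ex$end, strand = ex$strand, gene_id = ex$gene_id,
                   transcript_id = ex$transcript_id,
                   exon_number = ex$exon_number, stringsAsFactors = FALSE))
    rows <- rows[order(rows$chrom, rows$start, rows$end,
                       match(rows$type, c("gene", "transcript", "exon")),
                       rows$gene_id, rows$transcript_id,
                       rows$exon_number), , drop = FALSE]
    gr <- GenomicRanges::GRanges(
        seqnames = rows$chrom,
        ranges = IRanges::IRanges(start = rows$start + 1L, end = rows$end),
        strand = rows$strand)
    S4Vectors::mcols(gr)$source <- "cgsplice"
    S4Vectors::mcols(gr)$type <- rows$type
    S4Vectors::mcols(gr)$gene_id <- rows$gene_id
    S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
    S4Vectors::mcols(gr)$exon_number <- rows$exon_number
    rtracklayer::export(gr, path, format = "gtf")
    invisible(path)
}

#' Read poly(A) sites or domain intervals from BED6
#'
#' `readPolyABed` interprets the BED name field as the owning gene id and
#' the interval start as the cleavage position. `readDomainBed` interprets
#' the name field as the domain label. BED is natively 0-based half-open,
#' matching the internal convention, so no coordinate shift is applied.
#'
#' @param path BED6 file path
#' @return data.frame suitable for the corresponding
#'   [GenomeAnnotation-class] slot
#' @export
readPolyABed <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(gene_id = gr$name, chrom = as.character(GenomicRanges::seqnames(gr)),
               pos = GenomicRanges::start(gr) - 1L,
               strand = as.character(GenomicRanges::strand(gr)),
               stringsAsFactors = FALSE)
}

#' @rdname readPolyABed
#' @export
readDomainBed <- function(path) {
    gr <- rtracklayer::import(path, format = "bed")
    data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
               start = GenomicRanges::start(gr) - 1L,
               end = GenomicRanges::end(gr),
               label = gr$name, stringsAsFactors = FALSE)
}
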
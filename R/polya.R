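#' Test a sequence for a U/GU-rich downstream sequence element
#'
#' TRUE if the sequence contains a window of at least six nucleotides
#' consisting only of uracils and at most three interspersed,
#' non-adjacent guanines. Because any longer qualifying stretch contains
#' a qualifying 6-mer, the scan checks every 6-nt window: all characters
#' in {U, G}, no GG dinucleotide, and no more than three G.
#'
#' @param sequence character string (DNA or RNA alphabet; T is read as U)
#' @return logical flag
#' @examples
#' isDse("UUUUUU")   # TRUE
#' isDse("UUGGUU")   # FALSE: adjacent guanines
#' @export
isDse <- function(sequence) {
    s <- .asRNA(sequence)
    L <- nchar(s)
    if (L < 6L) return(FALSE)
    chars <- strsplit(s, "", fixed = TRUE)[[1]]
    for (i in seq_len(L - 5L)) {
        w <- chars[i:(i + 5L)]
        if (!all(w %in% c("U", "G"))) next
        g <- w == "G"
        if (sum(g) > 3L) next
        if (any(g[-6L] & g[-1L])) next
        return(TRUE)
    }
    FALSE
}

#' Scan the 3'-end signals around a poly(A) site
#'
#' Reports, in transcript orientation relative to the cleavage site:
#' canonical A(A/U)UAAA hexamers within the 50 bp immediately upstream,
#' UGUA motifs (the CFIm-recognized element) within 150 bp upstream, and
#' the presence of a U/GU-rich downstream sequence element ([isDse()])
#' within 50 bp downstream. Windows are truncated at chromosome ends; a
#' site outside the sequence is an error.
#'
#' @param ann a [GenomeAnnotation-class]
#' @param gene_id owning gene (determines strand)
#' @param site 0-based cleavage position
#' @param genome chromosome sequences
#' @param upCanonical,upUgua,downDse window sizes in bp (defaults 50,
#'   150, 50)
#' @return list: canonical_count, canonical, ugua_count, dse,
#'   n_annotated_sites (poly(A) sites recorded for the gene)
#' @export
findPolyaSignals <- function(ann, gene_id, site, genome,
                             upCanonical = 50L, upUgua = 150L,
                             downDse = 50L) {
    g <- ann@genes[ann@genes$gene_id == gene_id, ]
    if (nrow(g) != 1L) stop("unknown gene id '", gene_id, "'")
    chromLen <- nchar(as.character(genome[[g$chrom]]))
    if (site < 0 || site > chromLen)
        stop("poly(A) site outside sequence bounds")
    minus <- g$strand == "-"
    if (!minus) {
        up <- .fetchSeq(genome, g$chrom, max(0L, site - upUgua), site, "+")
        down <- .fetchSeq(genome, g$chrom, site,
                          min(chromLen, site + downDse), "+")
    } else {
        up <- .fetchSeq(genome, g$chrom, site,
                        min(chromLen, site + upUgua), "-")
        down <- .fetchSeq(genome, g$chrom, max(0L, site - downDse), site, "-")
    }
    upR <- .asRNA(up)
    canonWin <- substr(upR, max(1L, nchar(upR) - upCanonical + 1L),
                       nchar(upR))
    canonical <- length(gregexpr("A[AU]UAAA", canonWin)[[1]])
    if (gregexpr("A[AU]UAAA", canonWin)[[1]][1] == -1L) canonical <- 0L
    ugua <- length(gregexpr("UGUA", upR)[[1]])
    if (gregexpr("UGUA", upR)[[1]][1] == -1L) ugua <- 0L
    list(canonical_count = canonical, canonical = canonical > 0,
         ugua_count = ugua, dse = isDse(down),
         n_annotated_sites = sum(ann@polyASites$gene_id == gene_id))
}

#' Annotated poly(A) site counts per gene
#'
#' Tabulates the number of recorded poly(A) sites for each gene, the
#' quantity compared between conjoined-gene participants and the
#' background of all genes carrying at least one site.
#'
#' @param ann a [GenomeAnnotation-class]
#' @return named integer vector (genes with >= 1 site)
#' @export
polyASiteCounts <- function(ann) {
    if (nrow(ann@polyASites) == 0L) return(setNames(integer(), character()))
    tab <- table(ann@polyASites$gene_id)
    setNames(as.integer(tab), names(tab))
}
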
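## fetch [start, end) 0-based half-open from a genome, optionally
## reverse-complemented into transcript orientation
.fetchSeq <- function(genome, chrom, start, end, strand = "+") {
    s <- as.character(genome[[chrom]])
    out <- substr(s, start + 1L, end)
    if (strand == "-")
        out <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(out)))
    out
}

#' Extract the seven skipped-exon analysis regions
#'
#' Returns, in transcript orientation, the upstream constitutive exon,
#' the two halves of the upstream intron, the skipped exon itself, the
#' two halves of the downstream intron, and the downstream constitutive
#' exon. Each flanking intron contributes at most `intronCap` bp: an
#' intron no longer than the cap is split at its midpoint; a longer one
#' contributes `intronCap/2` bp adjacent to each of its two splice
#' sites. Intron-half names encode which splice site they adjoin: for
#' the upstream intron, `up5in` adjoins the upstream exon's 5' splice
#' site (donor) and `up3in` adjoins the skipped exon's 3' splice site
#' (acceptor).
#'
#' @param se list with chrom, strand, and upExon, seExon, dnExon (each
#'   length-2 c(start, end), 0-based half-open; "up" = 5' in transcript
#'   orientation)
#' @param genome chromosome sequences
#' @param intronCap maximum bp contributed per intron (default 600)
#' @return named character vector of 7 sequences: upExon, up5in, up3in,
#'   SE, dn5in, dn3in, dnExon
#' @export
extractSeRegions <- function(se, genome, intronCap = 600L) {
    minus <- se$strand == "-"
    ## genomic order of the three exons
    exs <- list(se$upExon, se$seExon, se$dnExon)
    if (minus) exs <- rev(exs)
    g1 <- exs[[1]]; g2 <- exs[[2]]; g3 <- exs[[3]]
    if (g1[2] > g2[1] || g2[2] > g3[1])
        stop("exons must be ordered and non-overlapping")
    halves <- function(lo, hi) {
        len <- hi - lo
        take <- min(len, intronCap)
        if (len <= intronCap) {
            mid <- lo + len %/% 2L
            list(left = c(lo, mid), right = c(mid, hi))
        } else {
            half <- intronCap %/% 2L
            list(left = c(lo, lo + half), right = c(hi - half, hi))
        }
    }
    in1 <- halves(g1[2], g2[1])  # genomic-left intron
    in2 <- halves(g2[2], g3[1])  # genomic-right intron
    fetch <- function(iv) .fetchSeq(genome, se$chrom, iv[1], iv[2], se$strand)
    if (!minus) {
        c(upExon = fetch(g1),
          up5in = fetch(in1$left),   # adjoins upstream exon donor site
          up3in = fetch(in1$right),  # adjoins SE acceptor site
          SE = fetch(g2),
          dn5in = fetch(in2$left),   # adjoins SE donor site
          dn3in = fetch(in2$right),  # adjoins downstream exon acceptor
          dnExon = fetch(g3))
    } else {
        ## transcript orientation runs genomic right -> left
        c(upExon = fetch(g3),
          up5in = fetch(in2$right),
          up3in = fetch(in2$left),
          SE = fetch(g2),
          dn5in = fetch(in1$right),
          dn3in = fetch(in1$left),
          dnExon = fetch(g1))
    }
}

#' Extract the four conjoined-gene analysis regions
#'
#' The penultimate and ultimate exons of the upstream participant and
#' the first and second exons of the downstream participant, in
#' transcript orientation, taken from each gene's longest annotated
#' transcript. Matched background sets are built from randomly selected
#' non-CG genes with at least four exons.
#'
#' @param cg list with upstream, downstream gene ids
#' @param ann a [GenomeAnnotation-class]
#' @param genome chromosome sequences
#' @return named character vector: upPenultimate, upLast, dnFirst,
#'   dnSecond
#' @export
extractCgRegions <- function(cg, ann, genome) {
    upEx <- .txExons(ann, .longestTranscript(ann, cg$upstream))
    dnEx <- .txExons(ann, .longestTranscript(ann, cg$downstream))
    if (nrow(upEx) < 2L || nrow(dnEx) < 2L)
        stop("CG participants must have at least two exons")
    fetch <- function(ex, i) .fetchSeq(genome, ex$chrom[1], ex$start[i],
                                       ex$end[i], ex$strand[1])
    c(upPenultimate = fetch(upEx, nrow(upEx) - 1L),
      upLast = fetch(upEx, nrow(upEx)),
      dnFirst = fetch(dnEx, 1L),
      dnSecond = fetch(dnEx, 2L))
}

## Kerby simple-difference rank-biserial correlation: proportion of
## favorable minus unfavorable (group > other vs <) pairs
.rankBiserial <- function(g, o) {
    fav <- sum(vapply(g, function(x) sum(o < x), numeric(1)))
    unf <- sum(vapply(g, function(x) sum(o > x), numeric(1)))
    (fav - unf) / (length(g) * length(o))
}

#' Motif-density enrichment between a cluster and the remaining events
#'
#' For every (region, motif) pair present on both sides with at least
#' `minN` observations each, pools the densities, rank-transforms them
#' (average ranks on ties), and applies a two-sided unequal-variance
#' (Welch) t-test on the ranks. P-values are Benjamini-Hochberg adjusted
#' across all tests of the comparison; the effect size is the Kerby
#' simple-difference rank-biserial correlation (positive = denser in the
#' cluster). Degenerate cells whose values are identical on both sides
#' yield p = 1 and effect 0.
#'
#' @param group,other long data.frames with columns region, motif,
#'   density (one row per event region)
#' @param minN minimum observations per side (default 3)
#' @param alpha adjusted-significance threshold (default 0.05)
#' @return data.frame: region, motif, n_group, n_other, effect, p,
#'   p_adj, significant
#' @export
densityEnrichment <- function(group, other, minN = 3L, alpha = 0.05) {
    keys <- intersect(unique(paste(group$region, group$motif, sep = "\r")),
                      unique(paste(other$region, other$motif, sep = "\r")))
    rows <- list()
    for (key in sort(keys)) {
        parts <- strsplit(key, "\r", fixed = TRUE)[[1]]
        g <- group$density[group$region == parts[1] & group$motif == parts[2]]
        o <- other$density[other$region == parts[1] & other$motif == parts[2]]
        if (length(g) < minN || length(o) < minN) next
        pooled <- rank(c(g, o))
        rg <- pooled[seq_along(g)]; ro <- pooled[-seq_along(g)]
        if (sd(rg) == 0 && sd(ro) == 0) {
            p <- 1; eff <- if (mean(g) == mean(o)) 0 else .rankBiserial(g, o)
            if (mean(g) != mean(o)) p <- 0  # complete separation, constant
        } else {
            p <- t.test(rg, ro, var.equal = FALSE)$p.value
            eff <- .rankBiserial(g, o)
        }
        rows[[length(rows) + 1L]] <- data.frame(
            region = parts[1], motif = parts[2], n_group = length(g),
            n_other = length(o), effect = eff, p = p,
            stringsAsFactors = FALSE)
    }
    if (length(rows) == 0L)
        return(data.frame(region = character(), motif = character(),
                          n_group = integer(), n_other = integer(),
                          effect = numeric(), p = numeric(),
                          p_adj = numeric(), significant = logical(),
                          stringsAsFactors = FALSE))
    res <- do.call(rbind, rows)
    res$p_adj <- p.adjust(res$p, method = "BH")
    res$significant <- res$p_adj < alpha
    rownames(res) <- NULL
    res
}

#' Deduplicate motifs by RBP family
#'
#' Keeps one motif per family: a motif belonging to the family's
#' representative member when one is present, otherwise the motif
#' significant (enriched or depleted) in the greatest number of regions;
#' ties break on the lexicographically smallest motif id.
#'
#' @param cells enrichment table from [densityEnrichment()]
#' @param familyMap data.frame with columns motif, family, rbp
#' @param representatives optional named character vector mapping family
#'   to its representative member's RBP name
#' @return character vector of retained motif ids
#' @export
dedupMotifFamilies <- function(cells, familyMap, representatives = NULL) {
    if (!all(unique(cells$motif) %in% familyMap$motif))
        stop("family map does not cover all motifs")
    nSig <- vapply(familyMap$motif, function(m)
        sum(cells$significant[cells$motif == m]), numeric(1))
    kept <- character()
    for (fam in sort(unique(familyMap$family))) {
        cand <- familyMap[familyMap$family == fam, , drop = FALSE]
        if (!is.null(representatives) && fam %in% names(representatives)) {
            repCand <- cand[cand$rbp == representatives[[fam]], , drop = FALSE]
            if (nrow(repCand)) cand <- repCand
        }
        cnt <- nSig[match(cand$motif, familyMap$motif)]
        kept <- c(kept, cand$motif[order(-cnt, cand$motif)][1L])
    }
    sort(kept)
}

#' Cluster motifs by their enrichment/depletion pattern
#'
#' Hierarchically clusters the signed effect-size rows (Euclidean
#' distance, average linkage) and groups motifs whose co-phenetic
#' distance is no greater than half the maximum co-phenetic distance
#' between any two motifs.
#'
#' @param effectMat motifs x regions matrix of signed effects (rownames
#'   = motif ids)
#' @return named integer vector of cluster labels
#' @export
clusterMotifPatterns <- function(effectMat) {
    if (nrow(effectMat) == 1L)
        return(setNames(1L, rownames(effectMat)))
    d <- dist(effectMat)
    h <- hclust(d, method = "average")
    cd <- cophenetic(h)
    cutree(h, h = max(cd) / 2)
}
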
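#' Conjoined-gene detection filter configuration
#'
#' Defaults mirror the read-through call filters used for high-confidence
#' conjoined-gene (CG) selection: both participants expressed at >= 50
#' reads, a full splice score of 4, donor and acceptor at annotated exon
#' boundaries, rule-based confidence >= 0.9, and same-strand in-cis
#' partners.
#'
#' @param minGeneExpressionReads minimum reads per participating gene
#' @param requireSpliceScore required splice score (0-4)
#' @param requireExonBoundaries require annotated donor/acceptor boundaries
#' @param minConfidence minimum rule-based confidence
#' @param sameStrand require co-oriented partners
#' @param minSplitReads minimum junction split reads
#' @return a list of class `CGFilterConfig`
#' @export
cgFilterConfig <- function(minGeneExpressionReads = 50,
                           requireSpliceScore = 4,
                           requireExonBoundaries = TRUE,
                           minConfidence = 0.9,
                           sameStrand = TRUE,
                           minSplitReads = 1) {
    stopifnot(minGeneExpressionReads >= 0, requireSpliceScore >= 0,
              minConfidence >= 0, minSplitReads >= 0)
    structure(list(minGeneExpressionReads = minGeneExpressionReads,
                   requireSpliceScore = requireSpliceScore,
                   requireExonBoundaries = requireExonBoundaries,
                   minConfidence = minConfidence,
                   sameStrand = sameStrand,
                   minSplitReads = minSplitReads),
              class = "CGFilterConfig")
}

## total reads assigned to a gene in one sample: junction reads whose
## donor or acceptor falls within the gene span, plus exonic reads from
## the coverage table (rows overlapping the gene's exons)
.geneExpression <- function(ann, gene_id, junctions, coverage, sample) {
    g <- ann@genes[ann@genes$gene_id == gene_id, ]
    j <- junctions[junctions$sample == sample & junctions$chrom == g$chrom, ,
                   drop = FALSE]
    inGene <- (j$donor >= g$start & j$donor <= g$end) |
              (j$acceptor >= g$start & j$acceptor <= g$end)
    reads <- sum(j$count[inGene])
    if (!is.null(coverage) && nrow(coverage)) {
        cv <- coverage[coverage$gene_id == gene_id &
                       coverage$sample == sample, , drop = FALSE]
        reads <- reads + sum(cv$mean_depth)
    }
    reads
}

#' Splice score of a candidate junction
#'
#' One point each for: donor at an annotated exon 3' boundary, acceptor at
#' an annotated exon 5' boundary, intronic sequence beginning with GT, and
#' ending with AG (both strand-aware; on the minus strand the reverse
#' complement of the genomic gap is checked). Without a genome sequence
#' only the two boundary points can be awarded.
#'
#' @param junction list/one-row data.frame with chrom, strand, donor,
#'   acceptor (0-based boundary coordinates; donor is the upstream exon's
#'   3' boundary)
#' @param ann a [GenomeAnnotation-class]
#' @param genome named character vector or `Biostrings::DNAStringSet` of
#'   chromosome sequences, or NULL
#' @return integer score 0-4
#' @export
spliceScore <- function(junction, ann, genome = NULL) {
    ex <- ann@exons[ann@exons$chrom == junction$chrom, , drop = FALSE]
    minus <- junction$strand == "-"
    lo <- min(junction$donor, junction$acceptor)
    hi <- max(junction$donor, junction$acceptor)
    donorOK <- if (minus) any(ex$start == junction$donor)
               else any(ex$end == junction$donor)
    accOK <- if (minus) any(ex$end == junction$acceptor)
             else any(ex$start == junction$acceptor)
    score <- sum(donorOK, accOK)
    if (!is.null(genome) && hi - lo >= 4) {
        seqs <- as.character(genome[[junction$chrom]])
        intron <- substr(seqs, lo + 1L, hi)  # 0-based half-open [lo, hi)
        if (minus)
            intron <- as.character(Biostrings::reverseComplement(
                Biostrings::DNAString(intron)))
        score <- score + (toupper(substr(intron, 1, 2)) == "GT") +
            (toupper(substr(intron, nchar(intron) - 1, nchar(intron))) == "AG")
    }
    as.integer(score)
}

## deterministic rule-based confidence standing in for a learned
## classifier probability
.cgConfidence <- function(score, boundary_ok, split_reads) {
    (score / 4) * ifelse(boundary_ok, 1, 0.5) * pmin(1, split_reads / 5)
}

#' Detect conjoined-gene events from junction evidence
#'
#' A junction whose donor lies within one gene and whose acceptor lies
#' within a distinct downstream gene on the same strand of the same
#' chromosome is a CG candidate; candidates where either gene is
#' encapsulated within the other are discarded, then the configured
#' filters (gene expression, splice score, exon boundaries, confidence)
#' are applied. Output is deterministically ordered by (chrom, donor,
#' acceptor, downstream).
#'
#' @param junctions data.frame with columns chrom, strand, donor,
#'   acceptor, sample, count
#' @param ann a [GenomeAnnotation-class]
#' @param coverage optional coverage data.frame (gene_id, region_start,
#'   region_end, sample, mean_depth) used for the expression filter and
#'   interrupted indices
#' @param genome chromosome sequences for splice-site scoring (see
#'   [spliceScore()])
#' @param cfg a [cgFilterConfig()]
#' @return data.frame of CG events: upstream, downstream, chrom, strand,
#'   donor, acceptor, sample, split_reads, splice_score, boundary_ok,
#'   confidence, up_skipped, dn_skipped
#' @export
detectCg <- function(junctions, ann, coverage = NULL, genome = NULL,
                     cfg = cgFilterConfig()) {
    if (nrow(junctions) == 0L)
        return(.emptyCgDf())
    if (!all(junctions$chrom %in% ann@genes$chrom))
        stop("junction references unknown chromosome: ",
             setdiff(junctions$chrom, ann@genes$chrom)[1])
    g <- ann@genes
    out <- list()
    for (i in seq_len(nrow(junctions))) {
        jn <- junctions[i, ]
        if (jn$count < cfg$minSplitReads) next
        upGenes <- .genesAtPosition(ann, jn$chrom, jn$donor)
        dnGenes <- .genesAtPosition(ann, jn$chrom, jn$acceptor)
        ## boundary coordinates may equal a gene end; accept boundary hits
        if (length(upGenes) == 0L)
            upGenes <- g$gene_id[g$chrom == jn$chrom & g$start < jn$donor &
                                 jn$donor <= g$end]
        if (length(dnGenes) == 0L)
            dnGenes <- g$gene_id[g$chrom == jn$chrom & g$start <= jn$acceptor &
                                 jn$acceptor < g$end]
        for (ug in upGenes) for (dg in dnGenes) {
            if (ug == dg) next
            ua <- g[g$gene_id == ug, ]; da <- g[g$gene_id == dg, ]
            if (cfg$sameStrand &&
                (ua$strand != da$strand || ua$strand != jn$strand)) next
            ## upstream participant must be 5' of the downstream one
            if (ua$strand == "+" && ua$start > da$start) next
            if (ua$strand == "-" && ua$start < da$start) next
            if (.encapsulated(ua, da) || .encapsulated(da, ua)) next
            sc <- spliceScore(jn, ann, genome)
            minus <- ua$strand == "-"
            ex <- ann@exons[ann@exons$chrom == jn$chrom, , drop = FALSE]
            bOK <- if (minus)
                any(ex$start == jn$donor & ex$gene_id == ug) &&
                any(ex$end == jn$acceptor & ex$gene_id == dg)
            else
                any(ex$end == jn$donor & ex$gene_id == ug) &&
                any(ex$start == jn$acceptor & ex$gene_id == dg)
            conf <- .cgConfidence(sc, bOK, jn$count)
            if (sc < cfg$requireSpliceScore) next
            if (cfg$requireExonBoundaries && !bOK) next
            if (conf < cfg$minConfidence) next
            eUp <- .geneExpression(ann, ug, junctions, coverage, jn$sample)
            eDn <- .geneExpression(ann, dg, junctions, coverage, jn$sample)
            if (eUp < cfg$minGeneExpressionReads ||
                eDn < cfg$minGeneExpressionReads) next
            skips <- tryCatch(
                classifySplicingPattern(list(upstream = ug, downstream = dg,
                                             donor = jn$donor,
                                             acceptor = jn$acceptor), ann),
                error = function(e) c(NA_integer_, NA_integer_))
            out[[length(out) + 1L]] <- data.frame(
                upstream = ug, downstream = dg, chrom = jn$chrom,
                strand = ua$strand, donor = jn$donor, acceptor = jn$acceptor,
                sample = jn$sample, split_reads = jn$count,
                splice_score = sc, boundary_ok = bOK, confidence = conf,
                up_skipped = skips[1], dn_skipped = skips[2],
                stringsAsFactors = FALSE)
        }
    }
    if (length(out) == 0L)
        return(.emptyCgDf())
    res <- do.call(rbind, out)
    res <- res[order(res$chrom, res$donor, res$acceptor, res$downstream), ,
               drop = FALSE]
    rownames(res) <- NULL
    res
}

.emptyCgDf <- function() {
    data.frame(upstream = character(), downstream = character(),
               chrom = character(), strand = character(), donor = integer(),
               acceptor = integer(), sample = character(),
               split_reads = integer(), splice_score = integer(),
               boundary_ok = logical(), confidence = numeric(),
               up_skipped = integer(), dn_skipped = integer(),
               stringsAsFactors = FALSE)
}

#' Count exons skipped by a conjoined-gene junction
#'
#' `up_skipped` is the number of annotated exons of the upstream
#' participant strictly 3' of the donor exon; `dn_skipped` the number of
#' downstream-participant exons strictly 5' of the acceptor exon, both on
#' the longest annotated transcript of each gene. The modal read-through
#' pattern — splicing from the second-to-last exon of the upstream gene to
#' the second exon of the downstream gene — encodes as (1, 1).
#'
#' @param cg list with upstream, downstream, donor, acceptor
#' @param ann a [GenomeAnnotation-class]
#' @return integer c(up_skipped, dn_skipped)
#' @export
classifySplicingPattern <- function(cg, ann) {
    upEx <- .txExons(ann, .longestTranscript(ann, cg$upstream))
    dnEx <- .txExons(ann, .longestTranscript(ann, cg$downstream))
    minus <- upEx$strand[1] == "-"
    dIdx <- if (minus) which(upEx$start == cg$donor)
            else which(upEx$end == cg$donor)
    aIdx <- if (minus) which(dnEx$end == cg$acceptor)
            else which(dnEx$start == cg$acceptor)
    if (length(dIdx) != 1L || length(aIdx) != 1L)
        stop("CG boundary not annotated on the reference transcripts")
    c(up_skipped = nrow(upEx) - dIdx, dn_skipped = aIdx - 1L)
}

#' Interrupted index of a conjoined-gene participant
#'
#' Ratio of mean read coverage over the portion of the participant that
#' the read-through transcript retains to mean coverage over the removed
#' portion, i.e. the gene's total vs wild-type-only expression. For the
#' upstream participant the retained portion is everything up to and
#' including the donor exon; for the downstream participant everything
#' from the acceptor exon onward. Zero coverage over the removed portion
#' yields `Inf` with attribute `"removed_zero" = TRUE`.
#'
#' @param coverage data.frame (gene_id, region_start, region_end, sample,
#'   mean_depth), one row per exon region
#' @param cg list with upstream, downstream, donor, acceptor
#' @param ann a [GenomeAnnotation-class]
#' @param participant `"up"` or `"dn"`
#' @param sample optional sample id to restrict coverage rows
#' @return numeric ratio (possibly `Inf`, flagged)
#' @export
interruptedIndex <- function(coverage, cg, ann, participant = c("up", "dn"),
                             sample = NULL) {
    participant <- match.arg(participant)
    gene <- if (participant == "up") cg$upstream else cg$downstream
    ex <- .txExons(ann, .longestTranscript(ann, gene))
    minus <- ex$strand[1] == "-"
    if (participant == "up") {
        idx <- if (minus) which(ex$start == cg$donor)
               else which(ex$end == cg$donor)
        if (length(idx) != 1L) stop("donor not at an annotated exon boundary")
        retained <- ex[seq_len(idx), , drop = FALSE]
        removed <- ex[setdiff(seq_len(nrow(ex)), seq_len(idx)), , drop = FALSE]
    } else {
        idx <- if (minus) which(ex$end == cg$acceptor)
               else which(ex$start == cg$acceptor)
        if (length(idx) != 1L) stop("acceptor not at an annotated exon boundary")
        retained <- ex[idx:nrow(ex), , drop = FALSE]
        removed <- ex[setdiff(seq_len(nrow(ex)), idx:nrow(ex)), , drop = FALSE]
    }
    if (nrow(retained) == 0L) stop("retained portion is empty")
    cv <- coverage[coverage$gene_id == gene, , drop = FALSE]
    if (!is.null(sample)) cv <- cv[cv$sample == sample, , drop = FALSE]
    meanCov <- function(part) {
        if (nrow(part) == 0L) return(NA_real_)
        rows <- cv[cv$region_start %in% part$start &
                   cv$region_end %in% part$end, , drop = FALSE]
        if (nrow(rows) == 0L) stop("coverage missing for gene '", gene, "'")
        w <- rows$region_end - rows$region_start
        sum(rows$mean_depth * w) / sum(w)
    }
    ret <- meanCov(retained)
    rem <- meanCov(removed)
    if (is.na(rem) || rem == 0)
        return(structure(Inf, removed_zero = TRUE))
    ret / rem
}

#' Splicing index of a conjoined-gene junction
#'
#' Number of concordant wild-type read pairs spanning the junction region
#' divided by the number of reads supporting the read-through splice
#' junction itself. A called CG must have support, so zero supporting
#' reads is an error.
#'
#' @param wildtypePairs concordant wild-type read-pair count
#' @param cgSupportReads CG junction-spanning read count (>= 1)
#' @return numeric ratio
#' @export
splicingIndex <- function(wildtypePairs, cgSupportReads) {
    if (any(cgSupportReads == 0))
        stop("a CG event must have junction support reads")
    wildtypePairs / cgSupportReads
}

#' Collapse conjoined-gene events to unique partner pairs
#'
#' Events sharing the ordered (upstream, downstream) gene pair collapse to
#' one record, ignoring donor/acceptor isoform variation; the number of
#' distinct junction isoforms and total split-read support are recorded.
#'
#' @param events CG event data.frame as returned by [detectCg()]
#' @return data.frame with upstream, downstream, n_isoforms, total_reads
#' @export
collapseCgPartners <- function(events) {
    if (nrow(events) == 0L)
        return(data.frame(upstream = character(), downstream = character(),
                          n_isoforms = integer(), total_reads = integer(),
                          stringsAsFactors = FALSE))
    key <- paste(events$upstream, events$downstream, sep = "\r")
    iso <- tapply(paste(events$donor, events$acceptor),
                  key, function(x) length(unique(x)))
    reads <- tapply(events$split_reads, key, sum)
    ks <- sort(names(iso))
    parts <- strsplit(ks, "\r", fixed = TRUE)
    data.frame(upstream = vapply(parts, `[`, "", 1),
               downstream = vapply(parts, `[`, "", 2),
               n_isoforms = as.integer(iso[ks]),
               total_reads = as.integer(reads[ks]),
               stringsAsFactors = FALSE)
}

#' Shared and exclusive conjoined-gene pair sets across datasets
#'
#' @param pairSets named list (>= 2) of character vectors of pair keys
#'   (e.g. `"GENE_A|GENE_B"`)
#' @return list with `shared_all` (in every dataset), `exclusive` (named
#'   list, pairs found only in that dataset), and `pairwise` (data.frame
#'   of pairwise intersection counts)
#' @export
cgOverlapSets <- function(pairSets) {
    if (length(pairSets) < 2L)
        stop("need at least two datasets")
    nm <- names(pairSets)
    if (is.null(nm)) nm <- paste0("set", seq_along(pairSets))
    pairSets <- lapply(pairSets, unique)
    names(pairSets) <- nm
    sharedAll <- Reduce(intersect, pairSets)
    exclusive <- lapply(seq_along(pairSets), function(i) {
        setdiff(pairSets[[i]], unique(unlist(pairSets[-i])))
    })
    names(exclusive) <- nm
    combos <- utils::combn(seq_along(pairSets), 2)
    pw <- data.frame(
        set_a = nm[combos[1, ]], set_b = nm[combos[2, ]],
        n_intersection = apply(combos, 2, function(ij)
            length(intersect(pairSets[[ij[1]]], pairSets[[ij[2]]]))),
        stringsAsFactors = FALSE)
    list(shared_all = sort(sharedAll), exclusive = lapply(exclusive, sort),
         pairwise = pw)
}
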
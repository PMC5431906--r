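## junction evidence for the toy pair: the read-through junction from
## exon A3's 3' boundary to exon B2's 5' boundary, plus within-gene
## background junctions giving both genes >= 50 assigned reads
toyJunctions <- function(cgCount = 10L) {
    rbind(
        data.frame(chrom = "chr1", strand = "+", donor = 600L,
                   acceptor = 1700L, sample = "s1", count = cgCount,
                   stringsAsFactors = FALSE),
        data.frame(chrom = "chr1", strand = "+",
                   donor = c(200L, 400L, 600L, 1600L, 1800L),
                   acceptor = c(300L, 500L, 700L, 1700L, 1900L),
                   sample = "s1", count = 40L, stringsAsFactors = FALSE))
}

test_that("a supported boundary junction between tandem genes is called", {
    ann <- toyAnnotation(); genome <- toyGenome()
    calls <- detectCg(toyJunctions(), ann, genome = genome)
    expect_equal(nrow(calls), 1L)
    expect_equal(calls$upstream, "GENEA")
    expect_equal(calls$downstream, "GENEB")
    expect_equal(calls$splice_score, 4L)
    expect_true(calls$boundary_ok)
    expect_equal(calls$confidence, 1)
    expect_equal(calls$up_skipped, 1L)  # modal second-to-last -> second
    expect_equal(calls$dn_skipped, 1L)
})

test_that("antisense and encapsulated partners are never called", {
    ann <- toyAnnotation(); genome <- toyGenome()
    ## flip GENEB to the minus strand
    annAS <- ann
    gs <- geneTable(ann); gs$strand[gs$gene_id == "GENEB"] <- "-"
    ex <- exonTable(ann)
    ex$strand[ex$gene_id == "GENEB"] <- "-"
    ex$exon_number[ex$gene_id == "GENEB"] <- 3:1
    annAS <- GenomeAnnotation(gs, transcriptTable(ann), ex)
    expect_equal(nrow(detectCg(toyJunctions(), annAS, genome = genome)), 0L)

    ## add a gene encapsulated inside GENEA and aim the junction at it
    g2 <- rbind(geneTable(ann),
                data.frame(gene_id = "GENEM", chrom = "chr1", start = 210L,
                           end = 290L, strand = "+",
                           stringsAsFactors = FALSE))
    tx2 <- rbind(transcriptTable(ann),
                 data.frame(transcript_id = "GENEM.t1", gene_id = "GENEM",
                            stringsAsFactors = FALSE))
    ex2 <- rbind(exonTable(ann),
                 data.frame(transcript_id = "GENEM.t1", gene_id = "GENEM",
                            chrom = "chr1", start = 210L, end = 290L,
                            strand = "+", exon_number = 1L,
                            stringsAsFactors = FALSE))
    annEnc <- GenomeAnnotation(g2, tx2, ex2)
    jEnc <- toyJunctions()
    jEnc$acceptor[1] <- 210L  # junction from GENEA into the nested gene
    jEnc$donor[1] <- 100L
    calls <- detectCg(jEnc, annEnc, genome = toyGenome())
    expect_false(any(calls$downstream == "GENEM"))
})

test_that("detection is invariant to junction row order and enforces filters", {
    ann <- toyAnnotation(); genome <- toyGenome()
    j <- toyJunctions()
    set.seed(3)
    jShuf <- j[sample(nrow(j)), ]
    expect_equal(detectCg(j, ann, genome = genome),
                 detectCg(jShuf, ann, genome = genome))
    ## expression filter: drop the background support below 50 reads
    jLow <- j; jLow$count[-1] <- 2L
    expect_equal(nrow(detectCg(jLow, ann, genome = genome)), 0L)
    expect_equal(nrow(detectCg(
        jLow, ann, genome = genome,
        cfg = cgFilterConfig(minGeneExpressionReads = 0))), 1L)
    ## split-read support below 5 lowers confidence under 0.9
    jFew <- j; jFew$count[1] <- 3L
    expect_equal(nrow(detectCg(jFew, ann, genome = genome)), 0L)
    expect_error(detectCg(transform(j, chrom = "chrUnknown"), ann,
                          genome = genome), "unknown chromosome")
})

test_that("splice score decomposes into boundary and dinucleotide points", {
    ann <- toyAnnotation(); genome <- toyGenome()
    jn <- list(chrom = "chr1", strand = "+", donor = 600L, acceptor = 1700L)
    expect_equal(spliceScore(jn, ann, genome), 4L)
    ## mutate the donor GT to GC: one point lost
    s <- as.character(genome[[1]])
    substr(s, 602, 602) <- "C"
    genomeGC <- Biostrings::DNAStringSet(setNames(s, "chr1"))
    expect_equal(spliceScore(jn, ann, genomeGC), 3L)
    ## off-boundary, non-canonical junction scores 0
    s2 <- chartr("GTA", "CCC", as.character(genome[[1]]))
    jnBad <- list(chrom = "chr1", strand = "+", donor = 617L,
                  acceptor = 1723L)
    expect_equal(spliceScore(jnBad, ann,
                             Biostrings::DNAStringSet(setNames(s2, "chr1"))),
                 0L)
    ## without a genome only boundary points are available
    expect_equal(spliceScore(jn, ann, NULL), 2L)
})

test_that("splicing-pattern skip counts use the reference transcript", {
    ann <- toyAnnotation()
    base <- list(upstream = "GENEA", downstream = "GENEB")
    expect_equal(unname(classifySplicingPattern(
        c(base, donor = 600L, acceptor = 1700L), ann)), c(1L, 1L))
    expect_equal(unname(classifySplicingPattern(
        c(base, donor = 800L, acceptor = 1500L), ann)), c(0L, 0L))
    expect_equal(unname(classifySplicingPattern(
        c(base, donor = 200L, acceptor = 1500L), ann)), c(3L, 0L))
    expect_error(classifySplicingPattern(
        c(base, donor = 601L, acceptor = 1700L), ann), "not annotated")
})

test_that("interrupted index is the retained/removed coverage ratio", {
    ann <- toyAnnotation()
    cg <- list(upstream = "GENEA", downstream = "GENEB", donor = 600L,
               acceptor = 1700L)
    mkCov <- function(depRetained, depRemoved) {
        ex <- exonTable(ann)
        a <- ex[ex$gene_id == "GENEA", ]
        data.frame(gene_id = "GENEA", region_start = a$start,
                   region_end = a$end, sample = "s1",
                   mean_depth = c(rep(depRetained, 3), depRemoved),
                   stringsAsFactors = FALSE)
    }
    expect_equal(interruptedIndex(mkCov(8, 2), cg, ann, "up"), 4.0)
    expect_equal(interruptedIndex(mkCov(5, 5), cg, ann, "up"), 1.0)
    izero <- interruptedIndex(mkCov(8, 0), cg, ann, "up")
    expect_true(is.infinite(izero))
    expect_true(attr(izero, "removed_zero"))
    ## scale invariance
    expect_equal(interruptedIndex(mkCov(80, 20), cg, ann, "up"), 4.0)
})

test_that("splicing index divides wild-type pairs by CG support", {
    expect_equal(splicingIndex(20, 5), 4.0)
    expect_equal(splicingIndex(0, 5), 0.0)
    expect_error(splicingIndex(20, 0), "support")
})

test_that("partner collapsing and cross-dataset overlap sets behave as set ops", {
    ev <- data.frame(
        upstream = c("A", "A", "B"), downstream = c("B", "B", "A"),
        donor = c(10L, 20L, 30L), acceptor = c(100L, 100L, 120L),
        split_reads = c(5L, 7L, 2L), stringsAsFactors = FALSE)
    col <- collapseCgPartners(ev)
    expect_equal(nrow(col), 2L)
    ab <- col[col$upstream == "A", ]
    expect_equal(ab$n_isoforms, 2L)
    expect_equal(ab$total_reads, 12L)
    expect_equal(nrow(collapseCgPartners(ev[0, ])), 0L)

    ov <- cgOverlapSets(list(d1 = c("X", "Y", "Z"), d2 = c("Y", "Z", "W")))
    expect_equal(ov$shared_all, c("Y", "Z"))
    expect_equal(ov$exclusive$d1, "X")
    expect_equal(ov$exclusive$d2, "W")
    expect_equal(ov$pairwise$n_intersection, 2L)
    ident <- cgOverlapSets(list(a = c("X", "Y"), b = c("X", "Y")))
    expect_equal(lengths(ident$exclusive), c(a = 0L, b = 0L))
    disj <- cgOverlapSets(list(a = "X", b = "Y"))
    expect_equal(length(disj$shared_all), 0L)
})
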
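test_that("PWM reader/writer round-trips and validates probabilities", {
    p1 <- hardConsensusPwm("TGCATG", id = "M01", rbp = "RBFOX1",
                           family = "RBFOX")
    p2 <- hardConsensusPwm("GAAGAA", id = "M02", rbp = "SRSF1",
                           family = "SR")
    path <- file.path(tempdir(), "motifs.pwm")
    writePwmSet(list(M01 = p1, M02 = p2), path)
    back <- readPwmSet(path)
    expect_equal(names(back), c("M01", "M02"))
    expect_equal(back$M01$mat, p1$mat, tolerance = 1e-9)
    expect_equal(back$M02$rbp, "SRSF1")
    expect_error(pwm("bad", "x", "f", matrix(0.3, 2, 4)), "sum to 1")
})

test_that("PWM scanning at 80% of max admits only near-consensus windows", {
    p <- hardConsensusPwm("TGCATG")
    seqHit <- paste0("AAAA", "TGCATG", "CCCC")
    expect_equal(scanPwm(seqHit, p), 5L)
    ## one mismatch fails at the hard-consensus 0.8 threshold
    expect_equal(length(scanPwm("AAAATGCAAGCCCC", p)), 0L)
    expect_equal(length(scanPwm("TG", p)), 0L)
    expect_equal(length(scanPwm("", p)), 0L)
    ## U is equivalent to T
    expect_equal(scanPwm("AAAAUGCAUGCCCC", p), 5L)
})

test_that("scanner agrees exactly with the brute-force all-windows oracle", {
    set.seed(13)
    soft <- pwm("S1", "R", "F", {
        m <- matrix(runif(6 * 4), 6, 4)
        m / rowSums(m)
    }, background = c(0.3, 0.2, 0.2, 0.3))
    hard <- hardConsensusPwm("TGCATG")
    for (i in 1:200) {
        s <- randomSeq(200)
        expect_identical(scanPwm(s, soft), brutePwmScan(s, soft))
        expect_identical(scanPwm(s, hard), brutePwmScan(s, hard))
    }
})

test_that("motif density is matches per base pair", {
    expect_equal(motifDensity(2, 100), 0.02)
    expect_equal(motifDensity(0, 250), 0)
    expect_equal(motifDensity(3, 150), 0.02)
    expect_error(motifDensity(1, 0), "positive")
})

test_that("SE region extraction caps and splits flanking introns correctly", {
    set.seed(3)
    chars <- sample(c("A", "C", "G", "T"), 4000, replace = TRUE)
    genome <- Biostrings::DNAStringSet(
        setNames(paste(chars, collapse = ""), "chr1"))
    ## exons: up 0-100, SE 1100-1200, dn 1300-1400 (up intron 1000 bp,
    ## dn intron 100 bp)
    se <- list(chrom = "chr1", strand = "+", upExon = c(0L, 100L),
               seExon = c(1100L, 1200L), dnExon = c(1300L, 1400L))
    reg <- extractSeRegions(se, genome, intronCap = 600L)
    expect_equal(names(reg), c("upExon", "up5in", "up3in", "SE", "dn5in",
                               "dn3in", "dnExon"))
    expect_equal(nchar(reg[["up5in"]]), 300L)
    expect_equal(nchar(reg[["up3in"]]), 300L)
    sstr <- as.character(genome[[1]])
    expect_equal(reg[["up5in"]], substr(sstr, 101, 400))    # donor-adjacent
    expect_equal(reg[["up3in"]], substr(sstr, 801, 1100))   # acceptor-adjacent
    expect_equal(nchar(reg[["dn5in"]]), 50L)                # midpoint split
    expect_equal(nchar(reg[["dn3in"]]), 50L)
    expect_equal(reg[["SE"]], substr(sstr, 1101, 1200))
    ## minus strand: transcript orientation reverses and complements
    seM <- list(chrom = "chr1", strand = "-", upExon = c(1300L, 1400L),
                seExon = c(1100L, 1200L), dnExon = c(0L, 100L))
    regM <- extractSeRegions(seM, genome, intronCap = 600L)
    rc <- function(x) as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(x)))
    expect_equal(regM[["SE"]], rc(substr(sstr, 1101, 1200)))
    expect_equal(regM[["upExon"]], rc(substr(sstr, 1301, 1400)))
})

test_that("CG region extraction returns terminal and leading exon pairs", {
    ann <- toyAnnotation(); genome <- toyGenome()
    reg <- extractCgRegions(list(upstream = "GENEA", downstream = "GENEB"),
                            ann, genome)
    sstr <- as.character(genome[[1]])
    expect_equal(reg[["upPenultimate"]], substr(sstr, 501, 600))
    expect_equal(reg[["upLast"]], substr(sstr, 701, 800))
    expect_equal(reg[["dnFirst"]], substr(sstr, 1501, 1600))
    expect_equal(reg[["dnSecond"]], substr(sstr, 1701, 1800))
    ## single-exon partner is an error
    g <- data.frame(gene_id = c("A1", "B1"), chrom = "chr1",
                    start = c(0L, 500L), end = c(100L, 900L), strand = "+",
                    stringsAsFactors = FALSE)
    tx <- data.frame(transcript_id = c("A1.t1", "B1.t1"),
                     gene_id = c("A1", "B1"), stringsAsFactors = FALSE)
    ex <- data.frame(transcript_id = c("A1.t1", "B1.t1", "B1.t1"),
                     gene_id = c("A1", "B1", "B1"), chrom = "chr1",
                     start = c(0L, 500L, 800L), end = c(100L, 600L, 900L),
                     strand = "+", exon_number = c(1L, 1L, 2L),
                     stringsAsFactors = FALSE)
    annS <- GenomeAnnotation(g, tx, ex)
    expect_error(extractCgRegions(list(upstream = "A1", downstream = "B1"),
                                  annS, genome), "two exons")
})

test_that("density enrichment reports Kerby effects and BH-adjusted p-values", {
    ## complete separation: effect exactly +1
    grp <- data.frame(region = "SE", motif = "M1",
                      density = seq(0.11, 0.30, length.out = 20))
    oth <- data.frame(region = "SE", motif = "M1",
                      density = seq(0.001, 0.10, length.out = 50))
    cell <- densityEnrichment(grp, oth)
    expect_equal(cell$effect, 1)
    expect_true(cell$significant)
    expect_equal(cell$p_adj, cell$p)  # single test: BH is identity

    ## identical distributions: effect 0
    same <- data.frame(region = "SE", motif = "M1", density = rep(0.02, 10))
    cell0 <- densityEnrichment(same, same)
    expect_equal(cell0$effect, 0)
    expect_equal(cell0$p, 1)

    ## rank-biserial identity with the Mann-Whitney U statistic
    set.seed(8)
    for (i in 1:10) {
        g <- runif(15); o <- runif(25)
        eff <- densityEnrichment(
            data.frame(region = "r", motif = "m", density = g),
            data.frame(region = "r", motif = "m", density = o))$effect
        U <- unname(suppressWarnings(wilcox.test(g, o)$statistic))
        expect_equal(eff, 2 * U / (15 * 25) - 1, tolerance = 1e-12)
    }

    ## null calibration: few significant cells for identical distributions
    set.seed(99)
    mkLong <- function(n) {
        do.call(rbind, lapply(sprintf("R%d", 1:4), function(r)
            do.call(rbind, lapply(sprintf("M%02d", 1:10), function(m)
                data.frame(region = r, motif = m,
                           density = rpois(n, 2) / 200)))))
    }
    sigRates <- replicate(5, mean(densityEnrichment(mkLong(60),
                                                    mkLong(120))$significant))
    expect_lte(mean(sigRates), 0.05)
})

test_that("family deduplication prefers representatives then region counts", {
    cells <- data.frame(
        region = rep(c("a", "b", "c", "d"), times = 4),
        motif = rep(c("M1", "M2", "M3", "M4"), each = 4),
        significant = c(TRUE, TRUE, TRUE, FALSE,   # M1: 3 regions
                        TRUE, FALSE, FALSE, FALSE, # M2: 1 region
                        TRUE, FALSE, FALSE, FALSE, # M3: 1
                        TRUE, FALSE, FALSE, FALSE),# M4: 1
        stringsAsFactors = FALSE)
    fam <- data.frame(motif = c("M1", "M2", "M3", "M4"),
                      family = c("F1", "F1", "F2", "F2"),
                      rbp = c("P1", "P2", "P3", "P4"),
                      stringsAsFactors = FALSE)
    ## count rule within F1; lexicographic tie-break within F2
    expect_equal(dedupMotifFamilies(cells, fam), c("M1", "M3"))
    ## representative member overrides counts
    expect_equal(dedupMotifFamilies(cells, fam,
                                    representatives = c(F1 = "P2")),
                 c("M2", "M3"))
    expect_error(dedupMotifFamilies(cells, fam[1:2, ]), "cover")
})

test_that("motif pattern clustering groups by half-max co-phenetic distance", {
    m <- rbind(A1 = c(1, 1, 1, 1), A2 = c(0.9, 1, 1, 1.1),
               B1 = c(-1, -1, -1, -1), B2 = c(-1.1, -1, -0.9, -1))
    cl <- clusterMotifPatterns(m)
    expect_equal(cl[["A1"]], cl[["A2"]])
    expect_equal(cl[["B1"]], cl[["B2"]])
    expect_false(cl[["A1"]] == cl[["B1"]])
    ## identical rows collapse to one cluster
    same <- matrix(1, 3, 4, dimnames = list(c("x", "y", "z"), NULL))
    expect_equal(length(unique(clusterMotifPatterns(same))), 1L)
    one <- matrix(1, 1, 4, dimnames = list("solo", NULL))
    expect_equal(unname(clusterMotifPatterns(one)), 1L)
})
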
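test_that("simulated annotation has the configured pair geometry and is deterministic", {
    cfg <- simulationConfig(nGenePairs = 10L, seed = 4L)
    sim <- simulateAnnotation(cfg)
    g <- geneTable(sim$annotation)
    expect_equal(nrow(g), 20L)
    expect_true(all(g$strand == "+"))
    expect_equal(nrow(sim$pairs), 10L)
    ## pairs are consecutive on the chromosome
    cp <- consecutiveGenePairs(sim$annotation, sameStrandOnly = TRUE)
    for (i in seq_len(nrow(sim$pairs)))
        expect_true(any(cp$upstream == sim$pairs$upstream[i] &
                        cp$downstream == sim$pairs$downstream[i]))
    ## byte-identical GTF for the same seed
    f1 <- file.path(tempdir(), "det1.gtf"); f2 <- file.path(tempdir(), "det2.gtf")
    writeAnnotation(simulateAnnotation(cfg)$annotation, f1)
    writeAnnotation(simulateAnnotation(cfg)$annotation, f2)
    expect_identical(readLines(f1), readLines(f2))
})

test_that("fixed intergenic length round-trips through the distance computation", {
    cfg <- simulationConfig(nGenePairs = 6L, intergenicLen = c(5000L, 5000L),
                            seed = 8L)
    sim <- simulateAnnotation(cfg)
    for (i in seq_len(nrow(sim$pairs))) {
        d <- intergenicDistance(sim$annotation, sim$pairs$upstream[i],
                                sim$pairs$downstream[i])
        expect_equal(as.integer(d), 5000L)
    }
})

test_that("dose-response profiles respect shape labels and noise level", {
    cfg0 <- simulationConfig(nASEvents = 30L, psiEffectSize = 0,
                             noiseSd = 0, seed = 2L)
    p0 <- simulateDoseResponseProfiles(cfg0)
    expect_true(all(p0$labels == "flat"))
    expect_true(all(apply(p0$psi, 1, function(r) length(unique(r)) == 1L)))

    cfgM <- simulationConfig(nASEvents = 60L, noiseSd = 0, seed = 3L)
    pm <- simulateDoseResponseProfiles(cfgM)
    dn <- pm$psi[pm$labels == "down", , drop = FALSE]
    expect_true(all(apply(dn, 1, function(r) all(diff(r) <= 0))))
    up <- pm$psi[pm$labels == "up", , drop = FALSE]
    expect_true(all(apply(up, 1, function(r) all(diff(r) >= 0))))
    expect_true(all(pm$psi >= 0 & pm$psi <= 1))

    ## folded-normal oracle: mean |noisy - noiseless| ~ sigma*sqrt(2/pi)
    cfgN <- simulationConfig(nASEvents = 400L, noiseSd = 0.05, seed = 5L)
    pn <- simulateDoseResponseProfiles(cfgN)
    madObs <- mean(abs(pn$psi - pn$noiseless))
    expect_equal(madObs, 0.05 * sqrt(2 / pi), tolerance = 0.1)
})

test_that("junction counts follow the Poisson-binomial sampling model", {
    psi1 <- matrix(1, 20, 4, dimnames = list(sprintf("e%02d", 1:20), 1:4))
    jc1 <- simulateJunctionCounts(psi1, depth = 50, seed = 1L)
    expect_true(all(jc1$k_exc == 0L))

    psi0 <- matrix(0.5, 500, 2, dimnames = list(sprintf("e%03d", 1:500), 1:2))
    jc0 <- simulateJunctionCounts(psi0, depth = 1000, seed = 2L)
    tot <- sum(jc0$k_inc + jc0$k_exc)
    frac <- sum(jc0$k_inc) / tot
    expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / tot))

    jcz <- simulateJunctionCounts(psi1, depth = 0, seed = 3L)
    expect_true(all(jcz$k_inc == 0L & jcz$k_exc == 0L))

    ## determinism
    expect_identical(simulateJunctionCounts(psi1, 50, seed = 9L),
                     simulateJunctionCounts(psi1, 50, seed = 9L))
})

test_that("read-through simulation emits only planted junctions, dose-responsively", {
    cfg <- simulationConfig(nGenePairs = 10L, seed = 6L)
    sim <- simulateAnnotation(cfg)

    rt0 <- simulateCgReadthrough(sim, rep(0, 7), cfg@doseGrid, depth = 50,
                                 nCg = 5L, seed = 1L)
    keys0 <- paste(rt0$junctions$donor, rt0$junctions$acceptor)
    expect_false(any(keys0 %in% paste(rt0$planted$donor, rt0$planted$acceptor)))

    ## every emitted CG junction (between two genes) is a planted one
    rt <- simulateCgReadthrough(sim, cfg@cgRateCurve, cfg@doseGrid,
                                depth = 100, nCg = 5L, seed = 2L)
    ann <- sim$annotation
    for (i in seq_len(nrow(rt$junctions))) {
        dGene <- geneTable(ann)$gene_id[
            geneTable(ann)$start <= rt$junctions$donor[i] &
            rt$junctions$donor[i] <= geneTable(ann)$end]
        aGene <- geneTable(ann)$gene_id[
            geneTable(ann)$start <= rt$junctions$acceptor[i] &
            rt$junctions$acceptor[i] <= geneTable(ann)$end]
        if (length(dGene) && length(aGene) && dGene[1] != aGene[1])
            expect_true(any(rt$planted$donor == rt$junctions$donor[i] &
                            rt$planted$acceptor == rt$junctions$acceptor[i]))
    }

    ## Monte-Carlo oracle: mean CG counts rise with a monotone rate curve
    means <- matrix(0, 20, 7)
    for (s in 1:20) {
        rts <- simulateCgReadthrough(sim, cfg@cgRateCurve, cfg@doseGrid,
                                     depth = 100, nCg = 5L, seed = 100L + s)
        cgRows <- merge(rts$junctions, rts$planted[, c("donor", "acceptor")],
                        by = c("donor", "acceptor"))
        agg <- tapply(cgRows$count, cgRows$sample, sum)
        means[s, ] <- agg[as.character(cfg@doseGrid)]
    }
    rho <- cor(colMeans(means), seq_len(7), method = "spearman")
    expect_gte(rho, 0.9)
})

test_that("motif planting hits the requested density and rejects infeasible requests", {
    set.seed(1)
    g <- Biostrings::DNAStringSet(setNames(
        paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE),
              collapse = ""), "chrM"))
    spec0 <- data.frame(chrom = "chrM", start = 0L, end = 600L,
                        consensus = "UGCAUG", density = 0,
                        stringsAsFactors = FALSE)
    expect_identical(as.character(plantMotifs(g, spec0, seed = 1L)[[1]]),
                     as.character(g[[1]]))

    counts <- vapply(1:5, function(s) {
        spec <- data.frame(chrom = "chrM", start = (s - 1L) * 600L,
                           end = s * 600L, consensus = "UGCAUG",
                           density = 0.01, stringsAsFactors = FALSE)
        g2 <- plantMotifs(g, spec, seed = s)
        region <- substr(as.character(g2[[1]]), (s - 1L) * 600L + 1L,
                         s * 600L)
        length(gregexpr("TGCATG", region, fixed = TRUE)[[1]][
            gregexpr("TGCATG", region, fixed = TRUE)[[1]] > 0])
    }, numeric(1))
    expect_true(all(counts >= 5 & counts <= 7))

    badSpec <- data.frame(chrom = "chrM", start = 0L, end = 600L,
                          consensus = "UGCAUG", density = 0.5,
                          stringsAsFactors = FALSE)
    expect_error(plantMotifs(g, badSpec, seed = 1L), "occupancy")
})

test_that("siRNA count simulation is seeded and planted effects are recoverable", {
    s1 <- simulateSirnaCounts(seed = 12L)
    s2 <- simulateSirnaCounts(seed = 12L)
    expect_identical(s1, s2)
    expect_equal(sum(s1$isControl), 4L)

    eff <- data.frame(treatment = "siRNA_01",
                      cg_id = sprintf("CG%03d", 1:10), fold = 5,
                      stringsAsFactors = FALSE)
    ok <- vapply(1:20, function(s) {
        sim <- simulateSirnaCounts(effects = eff, seed = 200L + s)
        norm <- upperQuartileNormalize(sim$counts)
        grp <- groupCgByControlDetection(sim$counts, sim$isControl)
        ret <- filterCgExpression(norm, grp, sim$isControl)
        sum(eff$cg_id %in% ret$cg_id[ret$treatment == "siRNA_01"]) >= 9
    }, logical(1))
    expect_gte(mean(ok), 0.95)
})

test_that("long-read simulation matches annotation exactly at zero jitter", {
    cfg <- simulationConfig(nGenePairs = 4L, exonsPerGene = c(6L, 6L),
                            seed = 10L)
    sim <- simulateAnnotation(cfg)
    rt <- simulateCgReadthrough(sim, rep(0.3, 7), cfg@doseGrid, depth = 100,
                                nCg = 2L, seed = 1L)
    lr <- simulateLongReads(sim$annotation, rt$planted, seed = 3L)
    expect_identical(lr, simulateLongReads(sim$annotation, rt$planted,
                                           seed = 3L))
    cgReads <- lr[startsWith(lr$source, "CG:"), ]
    for (i in seq_len(nrow(rt$planted)))
        expect_gte(validateCg(as.list(rt$planted[i, ]), cgReads), 1L)
    lrJ <- simulateLongReads(sim$annotation, rt$planted, jitterBp = 2L,
                             seed = 3L)
    cgReadsJ <- lrJ[startsWith(lrJ$source, "CG:"), ]
    for (i in seq_len(nrow(rt$planted)))
        expect_equal(validateCg(as.list(rt$planted[i, ]), cgReadsJ), 0L)
})
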
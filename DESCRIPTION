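Package: cgsplice
Title: Dose-Response Splicing Analysis and Conjoined-Gene Transcript Detection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and quantification of conjoined-gene (read-through)
    transcripts from splice-junction evidence, percent-spliced-in (PSI)
    estimation with Bayes factors for differential splicing, signed
    weighted-correlation clustering of PSI dose-response profiles with
    eigen-events, RNA-binding-protein motif-density enrichment across
    splicing-event regions, 3'-end signal scanning (poly(A) signal, UGUA,
    downstream U/GU-rich elements), long-read validation of conjoined-gene
    calls, and siRNA-screen conjoined-gene expression analysis. Includes a
    fully seeded synthetic-data generator (annotations, genome sequence,
    dose-responsive junction counts, planted read-through events, planted
    motifs, long reads, siRNA count tables) so the whole pipeline is
    testable end to end with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: AlternativeSplicing, RNASeq, GeneFusionDetection, Clustering,
    MotifAnnotation, Software
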
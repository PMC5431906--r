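#' @import methods
#' @importFrom stats approx cor cutree dist hclust mad median na.omit
#'   p.adjust phyper pnorm qbeta quantile rbinom rnorm rpois runif sd
#'   t.test prcomp setNames lm coef cophenetic
#' @importFrom utils head tail read.delim write.table
NULL

## internal empty prototypes --------------------------------------------------

.empty_gene_df <- function() {
    data.frame(gene_id = character(), chrom = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
}

.empty_tx_df <- function() {
    data.frame(transcript_id = character(), gene_id = character(),
               stringsAsFactors = FALSE)
}

.empty_exon_df <- function() {
    data.frame(transcript_id = character(), gene_id = character(),
               chrom = character(), start = integer(), end = integer(),
               strand = character(), exon_number = integer(),
               stringsAsFactors = FALSE)
}

.empty_polya_df <- function() {
    data.frame(gene_id = character(), chrom = character(), pos = integer(),
               strand = character(), stringsAsFactors = FALSE)
}

.empty_domain_df <- function() {
    data.frame(chrom = character(), start = integer(), end = integer(),
               label = character(), stringsAsFactors = FALSE)
}

#' Gene-model container
#'
#' Holds genes, transcripts and exons together with optional poly(A) sites
#' and protein-domain intervals. All coordinates are stored 0-based
#' half-open; GTF/BED input and output converts to and from the 1-based
#' inclusive convention of those formats. This object is the coordinate
#' authority for every other module: detection, PSI isoform construction,
#' region extraction and long-read mapping all resolve coordinates against
#' it.
#'
#' @slot genes data.frame with columns gene_id, chrom, start, end, strand.
#' @slot transcripts data.frame with columns transcript_id, gene_id.
#' @slot exons data.frame with columns transcript_id, gene_id, chrom,
#'   start, end, strand, exon_number (1-based in transcription order,
#'   i.e. exon 1 is the 5'-most exon of the transcript).
#' @slot polyASites data.frame with columns gene_id, chrom, pos, strand;
#'   pos is the cleavage position (0-based).
#' @slot domains data.frame with columns chrom, start, end, label.
#'
#' @seealso [loadAnnotation()], [writeAnnotation()], [simulateAnnotation()]
#' @export
setClass("GenomeAnnotation",
    representation(genes = "data.frame", transcripts = "data.frame",
                   exons = "data.frame", polyASites = "data.frame",
                   domains = "data.frame"),
    prototype(genes = .empty_gene_df(), transcripts = .empty_tx_df(),
              exons = .empty_exon_df(), polyASites = .empty_polya_df(),
              domains = .empty_domain_df()))

setValidity("GenomeAnnotation", function(object) {
    g <- object@genes; ex <- object@exons; tx <- object@transcripts
    msgs <- character()
    if (nrow(ex) > 0 && any(ex$start >= ex$end))
        msgs <- c(msgs, "exon start must be < end (0-based half-open)")
    if (nrow(g) > 0 && any(g$start >= g$end))
        msgs <- c(msgs, "gene start must be < end")
    if (nrow(ex) > 0) {
        if (!all(ex$transcript_id %in% tx$transcript_id))
            msgs <- c(msgs, "exon references unknown transcript")
        ix <- match(ex$gene_id, g$gene_id)
        if (anyNA(ix)) {
            msgs <- c(msgs, "exon references unknown gene")
        } else if (any(ex$start < g$start[ix] | ex$end > g$end[ix])) {
            bad <- which(ex$start < g$start[ix] | ex$end > g$end[ix])[1L]
            msgs <- c(msgs, sprintf(
                "exon %d of transcript '%s' lies outside the span of gene '%s'",
                ex$exon_number[bad], ex$transcript_id[bad], ex$gene_id[bad]))
        }
        ## exons must not overlap within a transcript
        for (t in unique(ex$transcript_id)) {
            e <- ex[ex$transcript_id == t, , drop = FALSE]
            e <- e[order(e$start), , drop = FALSE]
            if (nrow(e) > 1 && any(e$start[-1] < e$end[-nrow(e)])) {
                msgs <- c(msgs, sprintf(
                    "overlapping exons within transcript '%s'", t))
                break
            }
        }
    }
    if (length(msgs)) msgs else TRUE
})

#' @describeIn GenomeAnnotation compact summary
#' @param object a GenomeAnnotation
#' @export
setMethod("show", "GenomeAnnotation", function(object) {
    cat("GenomeAnnotation with", nrow(object@genes), "genes,",
        nrow(object@transcripts), "transcripts,",
        nrow(object@exons), "exons\n")
    if (nrow(object@polyASites)) cat(" ", nrow(object@polyASites),
                                     "poly(A) sites\n")
    if (nrow(object@domains)) cat(" ", nrow(object@domains),
                                  "domain intervals\n")
    invisible(NULL)
})

#' Construct a GenomeAnnotation from component tables
#'
#' @param genes,transcripts,exons,polyASites,domains data.frames as
#'   documented for the corresponding [GenomeAnnotation-class] slots.
#'   Coordinates are 0-based half-open.
#' @return a validated [GenomeAnnotation-class] object
#' @export
GenomeAnnotation <- function(genes, transcripts, exons,
                             polyASites = .empty_polya_df(),
                             domains = .empty_domain_df()) {
    new("GenomeAnnotation", genes = genes, transcripts = transcripts,
        exons = exons, polyASites = polyASites, domains = domains)
}

#' Simulation configuration
#'
#' Parameters of the synthetic-data generator. Defaults describe the study
#' conditions the generator emulates: a seven-point inhibitor concentration
#' grid, tandem same-strand gene pairs with multi-exon transcripts, a
#' dose-increasing read-through rate, and a mixture of monotone-up,
#' monotone-down and flat PSI dose curves.
#'
#' @slot nGenePairs integer, number of tandem same-strand gene pairs.
#' @slot exonsPerGene integer length-2 range.
#' @slot exonLen,intronLen,intergenicLen integer length-2 bp ranges
#'   (intergenicLen is the gap between the two genes of a pair).
#' @slot doseGrid numeric, strictly increasing concentration labels.
#' @slot depth numeric, expected junction reads per event per sample.
#' @slot cgRateCurve numeric per-dose read-through probability, in [0,1].
#' @slot nASEvents integer, number of alternative-splicing events simulated.
#' @slot psiShapeProps numeric length-3 (up, down, flat), sums to 1.
#' @slot psiEffectSize numeric, total PSI change across the grid for
#'   monotone events.
#' @slot noiseSd numeric, per-observation Gaussian PSI noise.
#' @slot seed integer.
#' @export
setClass("SimulationConfig",
    representation(nGenePairs = "integer", exonsPerGene = "integer",
                   exonLen = "integer", intronLen = "integer",
                   intergenicLen = "integer", doseGrid = "numeric",
                   depth = "numeric", cgRateCurve = "numeric",
                   nASEvents = "integer", psiShapeProps = "numeric",
                   psiEffectSize = "numeric", noiseSd = "numeric",
                   seed = "integer"))

setValidity("SimulationConfig", function(object) {
    msgs <- character()
    if (object@nGenePairs < 1L) msgs <- c(msgs, "nGenePairs must be >= 1")
    for (nm in c("exonsPerGene", "exonLen", "intronLen", "intergenicLen")) {
        r <- slot(object, nm)
        if (length(r) != 2L || any(r <= 0L) || r[1] > r[2])
            msgs <- c(msgs, sprintf("%s must be a positive low-high range", nm))
    }
    if (is.unsorted(object@doseGrid, strictly = TRUE))
        msgs <- c(msgs, "doseGrid must be strictly increasing")
    if (any(object@cgRateCurve < 0 | object@cgRateCurve > 1))
        msgs <- c(msgs, "cgRateCurve probabilities must lie in [0,1]")
    if (length(object@cgRateCurve) != length(object@doseGrid))
        msgs <- c(msgs, "cgRateCurve must have one rate per dose")
    if (abs(sum(object@psiShapeProps) - 1) > 1e-8 ||
        any(object@psiShapeProps < 0))
        msgs <- c(msgs, "psiShapeProps must be non-negative and sum to 1")
    if (object@depth < 0) msgs <- c(msgs, "depth must be >= 0")
    if (object@noiseSd < 0) msgs <- c(msgs, "noiseSd must be >= 0")
    if (length(msgs)) msgs else TRUE
})

#' @describeIn SimulationConfig compact summary
#' @param object a SimulationConfig
#' @export
setMethod("show", "SimulationConfig", function(object) {
    cat("SimulationConfig:", object@nGenePairs, "gene pairs,",
        object@nASEvents, "AS events,",
        length(object@doseGrid), "doses, depth", object@depth,
        ", seed", object@seed, "\n")
    invisible(NULL)
})

#' @param nGenePairs,exonsPerGene,exonLen,intronLen,intergenicLen,doseGrid
#'   see slots of [SimulationConfig-class]
#' @param depth,cgRateCurve,nASEvents,psiShapeProps,psiEffectSize,noiseSd,seed
#'   see slots of [SimulationConfig-class]
#' @return a validated SimulationConfig
#' @describeIn SimulationConfig constructor with study-condition defaults
#' @export
simulationConfig <- function(nGenePairs = 50L,
                             exonsPerGene = c(4L, 8L),
                             exonLen = c(120L, 300L),
                             intronLen = c(80L, 2000L),
                             intergenicLen = c(500L, 10000L),
                             doseGrid = c(0, 0.05, 0.1, 0.5, 1, 5, 10),
                             depth = 100,
                             cgRateCurve = c(0.01, 0.02, 0.05, 0.12,
                                             0.2, 0.3, 0.4),
                             nASEvents = 300L,
                             psiShapeProps = c(up = 1/3, down = 1/3,
                                               flat = 1/3),
                             psiEffectSize = 0.4,
                             noiseSd = 0.05,
                             seed = 1L) {
    new("SimulationConfig",
        nGenePairs = as.integer(nGenePairs),
        exonsPerGene = as.integer(exonsPerGene),
        exonLen = as.integer(exonLen),
        intronLen = as.integer(intronLen),
        intergenicLen = as.integer(intergenicLen),
        doseGrid = as.numeric(doseGrid),
        depth = as.numeric(depth),
        cgRateCurve = as.numeric(cgRateCurve),
        nASEvents = as.integer(nASEvents),
        psiShapeProps = as.numeric(psiShapeProps),
        psiEffectSize = as.numeric(psiEffectSize),
        noiseSd = as.numeric(noiseSd),
        seed = as.integer(seed))
}
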
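#' Beta-binomial PSI posterior from junction counts
#'
#' Percent-spliced-in is estimated from reads spanning the discriminating
#' junctions only: `kInc` inclusion-supporting and `kExc`
#' exclusion-supporting reads. Under a uniform Beta(1,1) prior the
#' posterior is Beta(kInc+1, kExc+1); the point estimate is the posterior
#' mean and the interval is the central 95% credible interval. Because
#' only junction-spanning reads are counted, isoform lengths do not enter
#' the model.
#'
#' @param kInc,kExc non-negative integer vectors (recycled)
#' @param level credible level (default 0.95)
#' @return data.frame with columns psi_mean, ci_low, ci_high, k_inc, k_exc
#' @examples
#' estimatePsi(30, 10)  # posterior mean 31/42
#' @export
estimatePsi <- function(kInc, kExc, level = 0.95) {
    if (any(kInc < 0) || any(kExc < 0))
        stop("counts must be non-negative")
    n <- max(length(kInc), length(kExc))
    kInc <- rep_len(kInc, n); kExc <- rep_len(kExc, n)
    a <- kInc + 1; b <- kExc + 1
    alpha <- (1 - level) / 2
    data.frame(psi_mean = a / (a + b),
               ci_low = qbeta(alpha, a, b),
               ci_high = qbeta(1 - alpha, a, b),
               k_inc = kInc, k_exc = kExc)
}

#' Bayes factor for differential PSI between two samples
#'
#' Marginal-likelihood ratio of the model with independent inclusion
#' fractions in the two samples over the model with a single shared
#' fraction, both under uniform priors:
#' \deqn{BF = \frac{B(k_1+1, n_1-k_1+1)\,B(k_2+1, n_2-k_2+1)}
#'                 {B(1,1)\,B(k_1+k_2+1,\; n_1+n_2-k_1-k_2+1)}}
#' with \eqn{B} the beta function; binomial coefficients cancel. The BF is
#' symmetric under sample swap; with no data it equals 1. Values >= 20 are
#' conventionally treated as evidence for differential splicing.
#'
#' @param k1,n1 inclusion count and junction-read total in sample 1
#' @param k2,n2 same for sample 2
#' @return numeric Bayes factor(s), vectorized
#' @examples
#' bayesFactorDeltaPsi(5, 10, 5, 10)   # ~0.505: same-proportion data
#' bayesFactorDeltaPsi(10, 10, 0, 10)  # ~3.2e4: complete separation
#' @export
bayesFactorDeltaPsi <- function(k1, n1, k2, n2) {
    if (any(c(k1, n1, k2, n2) < 0))
        stop("counts must be non-negative")
    if (any(k1 > n1) || any(k2 > n2))
        stop("inclusion count exceeds total")
    exp(lbeta(k1 + 1, n1 - k1 + 1) + lbeta(k2 + 1, n2 - k2 + 1) -
        lbeta(k1 + k2 + 1, n1 + n2 - k1 - k2 + 1))
}

#' Filter differential-splicing events
#'
#' Retains events meeting all of: Bayes factor >= `minBF`, |dPSI| >=
#' `minDelta`, both isoforms supported by at least one read in the
#' comparison, and the isoform read-support rule: with
#' `isoformReadRule = "each"` (default) each isoform must gather >=
#' `minIsoReads` reads summed over the two samples; with `"total"` the
#' two isoforms together must. Input order is preserved.
#'
#' @param events data.frame with columns bayes_factor, delta_psi, k_inc1,
#'   k_exc1, k_inc2, k_exc2
#' @param minBF minimum Bayes factor (default 20)
#' @param minDelta minimum |delta PSI| (default 0.1)
#' @param minIsoReads minimum isoform read support (default 10)
#' @param isoformReadRule `"each"` or `"total"`
#' @return the retained subset of `events`
#' @export
filterDeltaAS <- function(events, minBF = 20, minDelta = 0.1,
                          minIsoReads = 10,
                          isoformReadRule = c("each", "total")) {
    isoformReadRule <- match.arg(isoformReadRule)
    inc <- events$k_inc1 + events$k_inc2
    exc <- events$k_exc1 + events$k_exc2
    supp <- if (isoformReadRule == "each")
        inc >= minIsoReads & exc >= minIsoReads
    else inc + exc >= minIsoReads
    keep <- events$bayes_factor >= minBF &
        abs(events$delta_psi) >= minDelta &
        inc > 0 & exc > 0 & supp
    events[keep, , drop = FALSE]
}

#' Build inclusion/exclusion isoforms for a conjoined-gene event
#'
#' The inclusion (read-through) isoform consists of the splice-junction
#' adjacent exon of the upstream participant, any detected intergenic
#' exons, and the junction-adjacent exon of the downstream participant.
#' The exclusion (wild-type) isoform consists of the donor-adjacent exon
#' plus up to one further downstream exon of the upstream participant, if
#' one exists. The donor must sit at an annotated exon 3' boundary and
#' the acceptor at an annotated exon 5' boundary of the reference
#' (longest) transcripts.
#'
#' @param cg list or one-row data.frame with upstream, downstream, donor,
#'   acceptor (genomic bp, 0-based boundary coordinates)
#' @param ann a [GenomeAnnotation-class]
#' @param intergenicExons optional data.frame(start, end) of detected
#'   exons between the participants, in transcription order
#' @return list with elements `inclusion` and `exclusion`, each a
#'   data.frame(start, end) exon chain in transcription order
#' @export
buildCgIsoforms <- function(cg, ann, intergenicExons = NULL) {
    upTx <- .longestTranscript(ann, cg$upstream)
    dnTx <- .longestTranscript(ann, cg$downstream)
    upEx <- .txExons(ann, upTx)
    dnEx <- .txExons(ann, dnTx)
    minus <- upEx$strand[1] == "-"
    donorIdx <- if (minus) which(upEx$start == cg$donor)
                else which(upEx$end == cg$donor)
    accIdx <- if (minus) which(dnEx$end == cg$acceptor)
              else which(dnEx$start == cg$acceptor)
    if (length(donorIdx) != 1L || length(accIdx) != 1L)
        stop("CG donor/acceptor not at annotated exon boundaries of the ",
             "reference transcripts")
    donorExon <- upEx[donorIdx, c("start", "end")]
    accExon <- dnEx[accIdx, c("start", "end")]
    inclusion <- rbind(donorExon,
                       if (!is.null(intergenicExons))
                           intergenicExons[, c("start", "end")],
                       accExon)
    exclusion <- if (donorIdx < nrow(upEx))
        rbind(donorExon, upEx[donorIdx + 1L, c("start", "end")])
    else donorExon
    rownames(inclusion) <- rownames(exclusion) <- NULL
    list(inclusion = inclusion, exclusion = exclusion)
}

#' Build inclusion/exclusion isoforms for a retained (detained) intron
#'
#' Given an intron interval flanked by annotated exons, the inclusion
#' isoform is the contiguous exon-intron-exon block and the exclusion
#' isoform is the spliced two-exon chain. PSI for the event is then
#' estimated from retained-junction vs spliced junction reads with
#' [estimatePsi()].
#'
#' @param intron length-2 numeric (start, end), 0-based half-open
#' @param ann a [GenomeAnnotation-class]
#' @return list with `inclusion` and `exclusion` exon chains
#' @export
buildRiIsoforms <- function(intron, ann) {
    ex <- ann@exons
    up <- ex[ex$end == intron[1], , drop = FALSE]
    dn <- ex[ex$start == intron[2], , drop = FALSE]
    hit <- NULL
    for (i in seq_len(nrow(up))) {
        j <- which(dn$transcript_id == up$transcript_id[i] &
                   dn$exon_number == up$exon_number[i] + 1L)
        if (length(j) == 0L)  # minus strand: downstream exon has lower number
            j <- which(dn$transcript_id == up$transcript_id[i] &
                       dn$exon_number == up$exon_number[i] - 1L)
        if (length(j) >= 1L) { hit <- list(up = up[i, ], dn = dn[j[1L], ]); break }
    }
    if (is.null(hit))
        stop("intron (", intron[1], ", ", intron[2],
             ") is not flanked by adjacent annotated exons")
    list(inclusion = data.frame(start = hit$up$start, end = hit$dn$end),
         exclusion = data.frame(start = c(hit$up$start, hit$dn$start),
                                end = c(hit$up$end, hit$dn$end)))
}
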
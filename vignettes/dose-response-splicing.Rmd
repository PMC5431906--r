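---
title: "Dose-response splicing and conjoined-gene analysis with cgsplice"
author: "cgsplice authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-response splicing and conjoined-gene analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cgsplice)
```

# Overview

`cgsplice` implements a desk-scale, fully testable version of a
dose-response splicing analysis built around graded pharmacological
inhibition of the CDC-like kinases (CLKs). Increasing CLK inhibition
shifts alternative splicing (AS) — exon skipping, intron retention and
related event classes — and, unexpectedly, promotes *conjoined-gene*
(CG) transcripts: chimeric read-through products spliced between two
adjacent genes on the same strand, formed at the expense of the upstream
partner's canonical terminal exons. The package covers six analysis
stages and the synthetic-data generator that makes them verifiable:

1. **PSI quantification** — percent-spliced-in posteriors and Bayes
   factors from inclusion/exclusion junction counts.
2. **CG detection** — read-through calls from junction evidence between
   in-cis, same-strand gene pairs, with splice-score, exon-boundary,
   expression and confidence filters, plus the interrupted and splicing
   indices used to characterize calls.
3. **Dose-response clustering** — signed weighted-correlation networks
   over PSI (or expression) profiles, topological-overlap clustering,
   eigen-events and event-type enrichment.
4. **Slope concordance** — Huber-robust regression slopes across dose and
   a label-shuffling permutation test for cross-dataset agreement.
5. **Motif enrichment** — PWM scanning over defined event regions, motif
   densities, rank-based tests with rank-biserial effect sizes, family
   deduplication and enrichment-pattern clustering; plus 3'-end signal
   scanning (poly(A) hexamer, UGUA, downstream U/GU-rich element).
6. **siRNA screen analysis** — upper-quartile normalization and
   control-threshold filtering of CG counts across knockdown libraries.

# The models and their assumptions

## PSI posterior and Bayes factor

Only reads spanning the junctions that discriminate the two isoforms of
an event are counted, so isoform lengths play no role. With `k_inc`
inclusion and `k_exc` exclusion junction reads and a uniform prior, the
PSI posterior is Beta(k_inc+1, k_exc+1); `estimatePsi()` reports the
posterior mean and central 95% credible interval. Differential splicing
between two samples is scored by the analytic marginal-likelihood ratio
of independent-PSI over shared-PSI models (`bayesFactorDeltaPsi()`):

$$BF = \frac{B(k_1+1,\,n_1-k_1+1)\,B(k_2+1,\,n_2-k_2+1)}
            {B(1,1)\,B(k_1+k_2+1,\,n_1+n_2-k_1-k_2+1)}.$$

Binomial coefficients cancel, the statistic is symmetric under sample
swap, and with no data it equals 1. Events are retained by
`filterDeltaAS()` when BF &ge; 20, |&Delta;PSI| &ge; 0.1, both isoforms
have nonzero support and each isoform reaches 10 reads. The phrase
"fewer than 10 reads supporting either isoform" is genuinely ambiguous;
the default reads it as *each isoform needs 10 reads*, and
`isoformReadRule = "total"` gives the other reading.

This junction-only beta-binomial model deliberately replaces a full
generative isoform model (read-length and isoform-length corrections,
read-assignment sampling): it is closed-form, exactly testable, and its
calibration is verified on simulated data (mean absolute error of the
posterior mean &le; 0.03 at ~200 reads; interval coverage 0.95 ± 0.03).

## CG detection

A splice junction whose donor falls in one gene and whose acceptor falls
in a distinct downstream gene is a CG candidate when the genes are
co-oriented on one chromosome and neither is encapsulated within the
other (a nested gene, e.g. an intronic miRNA, is never a CG partner).
Filters mirror high-confidence read-through selection: both genes
expressed (&ge; 50 assigned reads), splice score 4 (donor boundary,
acceptor boundary, GT.., ..AG), annotated exon boundaries, and a
rule-based confidence &ge; 0.9. The confidence replaces a learned
classifier probability with a transparent deterministic rule: full marks
when score 4, boundaries annotated and &ge; 5 split reads, otherwise
proportionally reduced. Gene expression is measured as junction reads
assigned to the gene plus exonic coverage reads; the accounting is a
package convention, stated here because no single standard exists.

Two per-call indices describe the dose of read-through: the
*interrupted index* (mean coverage over the portion of a participant
retained by the CG divided by the removed portion — total vs wild-type
expression), and the *splicing index* (wild-type junction-spanning read
pairs divided by CG junction reads). Both are scale-invariant in
coverage.

## Long-read validation

Long reads are junction chains with aligned-proportion and identity
attributes; reads below 90% aligned proportion or 80% identity are
discarded. A read maps to a gene when at least three of its junctions
exactly match that gene's annotated junctions; a read mapping to exactly
two co-oriented genes yields a CG candidate. A read validates a
short-read CG call when one of its junctions equals the call's
donor/acceptor pair *exactly* — the strictest reading of
junction-coordinate matching. A tolerance window exists
(`validateCg(..., tolerance =)`) but defaults to 0; 2 bp of simulated
jitter therefore yields zero validations, by design.

## Signed network clustering of dose profiles

Profiles (rows) over the ordered dose grid are row-standardized;
the signed adjacency $a_{ij} = ((1+\mathrm{cor}_{ij})/2)^\beta$ maps
correlation 1 to 1 and correlation −1 to 0, so anti-correlated responses
never cluster together. The exponent $\beta$ is chosen by scale-free
topology fit over candidates 1–30 (`selectSoftThreshold()`): the
smallest candidate whose fit R² exceeds 0.8 as the curve plateaus
(step change < 0.01). Dose-response designs rarely reach R² 0.8; in that
case a value above 20 is selected at the plateau of the fit curve, which
on the synthetic designs used here typically lands between 21 and 30.
Adjacency is converted to topological-overlap similarity, clustered by
average linkage on 1−TOM with a *static* tree cut (0.99 of the maximum
merge height) and a minimum module size of 25. A dynamic branch-cutting
heuristic would add stochastic tuning surface for little benefit at this
scale; the static cut is deterministic and order-invariant. Modules
whose eigen-events correlate above 0.8 are merged (merge height 0.2, the
common default of the referenced merging step; the height is not dictated
by the analysis it mirrors). The *eigen-event* is the first principal
component of the member profiles, oriented to correlate positively with
the member average and scaled to unit variance; members correlating
below 0.75 with their eigen-event are unassigned. That threshold is a
hard invariant of the output, checked in the tests.

Event-class composition of each cluster is tested with a one-tailed
hypergeometric tail probability, BH-adjusted across all cluster × type
tests. Expression-profile clustering reuses the same machinery after the
eligibility filter `filterExpressionProfiles()` (expression &ge; 1 in
&ge; 4 libraries and &ge; 2-fold change somewhere).

## Slope concordance between datasets

Per-event dose slopes are fit by iteratively reweighted least squares
with Huber's T criterion (tuning constant 1.345, MAD scale), which
downweights outlying doses; the regression axis is the 0-based index of
the dose in the ordered grid, a monotone transform that preserves the
slope *sign* — the only quantity used — and avoids the singularity of a
log axis at dose 0. Concordance between two datasets is the proportion
of shared events with equal slope sign (exact-zero slopes are excluded
from the denominator; all-tie input is an error). Its p-value is
$p = (b+1)/(m+1)$ over $m$ label shuffles, where $b$ counts shuffles
reaching at least the observed proportion — so $p$ can never drop below
$1/(m+1)$. For seven or fewer events the test can enumerate all
permutations exactly. One calibration caveat is worth recording: the
concordance proportion is discrete, so with only tens of shared events
the tie mass makes $p$ conservative; at the scale this analysis is meant
for (thousands of shared events) the statistic is effectively continuous
and $p$ is uniform under the null, which the acceptance checks verify.

## Motif density and enrichment

Seven regions are taken per skipped-exon event — the two flanking
constitutive exons, the skipped exon, and two halves of each flanking
intron, capped at 600 bp per intron (≤ 300 bp adjacent to each splice
site; an intron under the cap is split at its midpoint). The cap is
interpreted *per intron*; the alternative per-half reading is available
through `intronCap`. For CG events the four regions are the upstream
participant's penultimate and last exons and the downstream
participant's first and second exons; the matched background is drawn
from non-CG genes with at least four exons. Scanning is sense-strand
only (RBP motifs act on the transcript), with log-odds scores corrected
for background nucleotide rates and a match threshold of 80% of the
PWM's maximum achievable score. Each passing window counts as a match;
the motif density of a region is matches per bp. Cluster-vs-rest
differences per (region, motif) are tested by a Welch t-test on pooled
ranks (robust to the zero-inflated, tied densities typical of short
regions), BH-adjusted within the comparison, with the Kerby
simple-difference rank-biserial correlation as effect size (equal to
$1 - 2U/(n_1 n_2)$, verified numerically). Families contribute one motif
each — the representative member's motif when present, otherwise the one
significant in most regions — and enrichment patterns are grouped by
cutting an average-linkage dendrogram at half the maximum co-phenetic
distance.

## 3'-end signals

Relative to a poly(A) cleavage site, in transcript orientation:
canonical A(A/U)UAAA hexamers are sought within 50 bp upstream, UGUA
(CFIm) motifs within 150 bp upstream, and a downstream sequence element
(DSE) within 50 bp downstream. A DSE is a stretch of at least six
nucleotides of uracils with up to three interspersed, non-adjacent
guanines; any longer qualifying stretch contains a qualifying 6-mer, so
the detector scans 6-nt windows, which the tests prove equivalent to
full substring enumeration.

## siRNA screen

CG supporting-read counts per library are upper-quartile normalized
(each library scaled by its 75th percentile of nonzero counts, times the
mean percentile across libraries — idempotent and scale-preserving).
CGs split into three groups by control detection (nonzero raw count):
detected in &ge; 3 controls, detected in none, and other. Group-1
treatment values are retained above the control mean + 2 sample SDs
(computed on normalized values, consistent with normalization preceding
filtering); group-2 CGs are assumed unexpressed in controls, so any
positive value is retained; other values are discarded. Retained
distinct CGs are counted per treatment. Note that with few control
libraries the mean + 2 SD rule's false-positive rate exceeds the
asymptotic Gaussian tail (≈ 2.3%) because the mean and SD are estimated;
the tests compare against a Monte-Carlo oracle of the rule itself at the
configured control count.

# The synthetic-data generator

`simulationConfig()` fixes the study conditions; its defaults are the
conditions every test and acceptance check runs under, chosen once:

* a seven-point dose grid (0, 0.05, 0.1, 0.5, 1, 5, 10 — arbitrary µM
  labels mirroring an inhibitor concentration series);
* tandem plus-strand gene pairs, 4–8 exons per gene, exon lengths
  120–300 bp, introns 80–2000 bp, intergenic gaps 0.5–10 kb;
* junction-read depth 100 per event and sample
  (n ~ Poisson, inclusion ~ Binomial(n, PSI); counts conserve totals);
* a monotone read-through rate curve rising from 0.01 to 0.4 across the
  grid; CG junction reads are *stolen* from the upstream gene's terminal
  junction rather than added, because read-through forms at the expense
  of canonical transcripts — the quantitative trade-off is not dictated
  by the analysis this emulates, so the steal model is a package
  construction, configurable through the rate curve;
* PSI curves: one third monotone-up, one third monotone-down, one third
  flat, total effect 0.4 across the grid, Gaussian noise sd 0.05
  (0.1 in the clustering checks, the harder condition);
* siRNA controls: 4 control libraries, near-Gaussian counts
  (mean 100, sd 20), library scale factors 0.5–2.

Every generator is a pure function of (config, seed) and restores the
caller's RNG state. Planted motif positions are drawn uniformly without
overlap, with colliding draws re-drawn up to a cap and an error beyond
it, so the density arithmetic stays exact.

What the generator does *not* emulate: read-level sequences and error
profiles, fragment-length and positional biases, overdispersion beyond
Poisson-binomial counting noise, correlated events on shared transcripts,
and genuine genomic sequence composition (background is i.i.d. uniform
except where motifs are planted). Passing tests therefore demonstrate
correctness of the statistical machinery under the stated sampling
model, not robustness to every artefact of real RNA-seq libraries.

# Numerical choices and degenerate inputs

* Coordinates are 0-based half-open internally; GTF I/O converts to
  1-based inclusive and the round trip is exact. BED is already 0-based.
* Overlapping adjacent genes get intergenic distance 0 with an overlap
  flag, keeping distance distributions non-negative.
* Zero-variance profile rows are an error for clustering (they have no
  correlation structure); all-missing rows are dropped with a message.
* An interrupted index with zero removed-portion coverage returns `Inf`
  flagged `removed_zero`; a splicing index with zero CG support is an
  error (a call must have support).
* Ties: detection output is ordered by (chrom, donor, acceptor,
  downstream gene); family deduplication breaks ties lexicographically;
  cluster ids are renumbered by decreasing size.
* Skip counts (`up_skipped`/`dn_skipped`) are computed on the longest
  annotated transcript of each partner and encode the modal
  second-to-last → second exon pattern as (1, 1). The encoding is a
  declared convention, convertible if a 0-based variant is preferred.
* PWM probabilities are floored at 1e-3 before log-odds; windows with
  non-ACGT characters never match.

# Problem sizes used in the checks

The test and acceptance runs use problem sizes chosen to exercise each
property well inside a desktop budget: 500 events at ~200 reads for PSI
calibration; 1000 events for the Bayes-factor null; a 200-pair genome
with 50 planted CGs for detection exactness; 450 profiles (150 per
shape) at noise 0.1 for clustering recovery; 200 replicates of 199
shuffles over 1000 events for permutation calibration; 20 seeds of a
100-vs-400-event design with 8 PWMs over 250-bp regions for enrichment
power; and 10,000 random sequences per scanner-oracle comparison.

# Known limitations

* The PSI model ignores isoform-length and positional read biases; PSI
  values from length-confounded designs will differ from generative
  models that correct for them.
* The rule-based CG confidence is transparent but untrained; on real
  data a calibrated classifier would discriminate better near the
  decision boundary.
* The static tree cut can split one diffuse module into two where a
  dynamic cutter would not; the merge step recovers most such splits.
* Exact junction matching for long-read validation is deliberately
  strict; alignment wobble in real long reads would require the
  tolerance option.
* Hypergeometric enrichment treats events as exchangeable; shared
  transcripts between events violate that mildly.
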
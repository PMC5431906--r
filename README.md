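# cgsplice

Dose-response splicing analysis and conjoined-gene transcript detection.

Graded inhibition of the CDC-like kinases (CLKs) reshapes alternative
splicing (AS) — exon skipping, intron retention and related event
classes shift monotonically with dose — and promotes **conjoined-gene
(CG) transcripts**: chimeric read-through products spliced between two
adjacent, same-strand genes in cis, formed at the expense of the
upstream partner's canonical terminal exons. `cgsplice` is an R package
for analysts working with junction-level RNA-seq evidence from such
dose-series experiments. It provides:

* **PSI quantification** — percent-spliced-in (ψ) posteriors from
  inclusion/exclusion junction counts under a Beta(k_inc+1, k_exc+1)
  posterior, and an analytic Bayes factor for differential splicing,

  BF = B(k₁+1, n₁−k₁+1) · B(k₂+1, n₂−k₂+1) / B(k₁+k₂+1, n₁+n₂−k₁−k₂+1),

  with the standard retention filter (BF ≥ 20, |ΔPSI| ≥ 0.1, isoform
  read support);
* **CG detection** from splice-junction tables between in-cis
  same-strand gene pairs (splice score, exon-boundary, expression and
  confidence filters; interrupted and splicing indices; splicing-pattern
  classification; partner collapsing and cross-dataset overlap sets);
* **long-read validation** of CG calls by exact junction-chain matching;
* **dose-response clustering** with a signed weighted-correlation
  network (a_ij = ((1+cor)/2)^β), topological overlap, eigen-events and
  hypergeometric event-type enrichment;
* **slope concordance** across datasets via Huber-robust regression and
  a label-shuffling permutation test, p = (b+1)/(m+1);
* **RBP motif enrichment** — PWM scanning at 80% of the maximum score
  over seven skipped-exon regions or four CG regions, motif density
  d = m/l, Welch tests on ranks with BH adjustment and Kerby
  rank-biserial effect sizes, family deduplication, pattern clustering;
  poly(A)-signal / UGUA / downstream-element scanning;
* **siRNA screen analysis** — upper-quartile normalization, control
  detection grouping and the mean + 2 SD expression filter;
* a fully seeded **synthetic-data generator** (GTF/FASTA/TSV out) so the
  entire pipeline is testable end to end with known ground truth.

## Worked example

Simulate a 20-pair genome with 8 planted read-through events, detect
them, and quantify one event's PSI across the dose grid:

```r
library(cgsplice)

cfg <- simulationConfig(nGenePairs = 20L, seed = 3L,
                        exonsPerGene = c(5L, 7L))
sim <- simulateAnnotation(cfg)
rt  <- simulateCgReadthrough(sim, cgRateCurve = rep(0.3, 7),
                             doseGrid = cfg@doseGrid, depth = 100,
                             nCg = 8L, seed = 5L)

calls <- detectCg(rt$junctions, sim$annotation, rt$coverage, sim$genome)
pairsCalled <- unique(paste(calls$upstream, calls$downstream))
pairsTruth  <- paste(rt$planted$upstream, rt$planted$downstream)
mean(pairsCalled %in% pairsTruth)   # precision
#> [1] 1
mean(pairsTruth %in% pairsCalled)   # recall
#> [1] 1
table(calls$up_skipped, calls$dn_skipped)
#>    
#>      1
#>   1 56
```

All 56 per-sample calls show the modal read-through pattern — splicing
from the upstream gene's second-to-last exon to the downstream gene's
second exon, encoded as `(up_skipped, dn_skipped) = (1, 1)`. The
interrupted index of the first planted event at the top dose,

```r
cg <- as.list(rt$planted[1, ])
interruptedIndex(rt$coverage, cg, sim$annotation, "up", sample = "10")
#> [1] 1.403509
```

is the upstream gene's total/wild-type coverage ratio; with a
read-through rate of 0.3 the expectation is 1/(1−0.3) ≈ 1.43. PSI
estimation and differential filtering work on any inclusion/exclusion
count table:

```r
estimatePsi(30, 10)
#>    psi_mean    ci_low   ci_high k_inc k_exc
#> 1 0.7380952 0.5979827 0.8565395    30    10
bayesFactorDeltaPsi(10, 10, 0, 10)
#> [1] 32065.09
```

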
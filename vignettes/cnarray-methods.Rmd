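---
title: "Gene-level copy number with cnarray: model, parameters, and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-level copy number with cnarray}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

Array-CGH platforms report a log2 tumor-vs-reference ratio per probe
(0 = copy-neutral, positive = gain, negative = loss). `cnarray`
summarizes probes to genes in three steps.

**Pseudogene extension.** Copy-number events typically span far more
than a gene body (commonly 1 kb to megabases), so probes well outside a
gene still carry its copy-number state. Each gene interval is widened
into a capture window — the *pseudogene* — by `flank` base pairs on both
sides plus `promoter` base pairs on the upstream side. Coordinates are
1-based inclusive throughout (genome-browser convention); BED export
converts to 0-based half-open.

**Base matrix.** A sparse genes × probes matrix `C` encodes membership:
a probe belongs to a pseudogene when they share at least one base pair
on the same chromosome. Under the *binary* scheme member weights are 1;
under the *averaged* scheme they are `1/k`, `k` being the gene's
member-probe count, so that every nonzero row sums to 1. Membership is
computed with an indexed interval query per chromosome
(`GenomicRanges::findOverlaps`), never an all-pairs scan; the test suite
checks the result against a naive all-pairs oracle exactly.

**CNAR product.** The gene-level matrix is `CNAR = C %*% D` for the
probes × samples matrix `D`: the sum (binary) or mean (averaged) of
member-probe values per gene and sample. Nothing downstream depends on
which scheme was used — both are first-class, and the scheme is recorded
as provenance on the result — but the averaged scheme keeps values on
the log2-ratio scale and is what the examples use.

## Parameters that matter

| parameter | default | units | why |
|---|---|---|---|
| `flank` | 100,000 | bp | window for copy-number events larger than the gene; at ~1 gene per 100–200 kb this captures the local event without swallowing the whole chromosome |
| `promoter` | 2,000 | bp | upstream regulatory allowance |
| `overlapRule` | `any` | — | ≥ 1 bp overlap; `within` and `midpoint` available for stricter membership |
| variance cutoff | 0.4 | log2² | conventional screen for genes that vary across a cohort |
| Fisher `epsilon` | 1e-12 | log2² | keeps zero-variance genes finite (score `1/epsilon` when means differ by 1); `epsilon = 0` restores `Inf` |
| SVM `cost` | 1 | — | fixed soft-margin regularization; the LOOCV protocol, not the learner, is the contract, and the classifier is pluggable |
| consensus resamples / fraction | 100 / 0.8 | — | common subsampling practice; base clusterer is hierarchical agglomerative with average linkage on Euclidean distances |

Design points that were genuinely open, and the choices made:

* **Promoter strandedness.** The promoter allowance is applied on the
  strand-aware upstream side; genes of unknown strand get it on both
  sides, and `strandAwarePromoter = FALSE` forces the symmetric variant
  for replication of strand-agnostic pipelines.
* **Gene deduplication.** Annotation exports carry duplicate symbols;
  one record is kept per symbol — longest span, then smallest start,
  then lexicographically smallest chromosome — a deterministic rule
  that makes parsing idempotent.
* **Missing probes.** A missing probe is excluded from its gene's
  sum/mean; averaged weights are renormalized over the observed member
  probes, preserving the mean-of-members semantics. A gene with no
  member probes, or all members missing in a sample, is `NA` rather
  than silently 0 (0 would mean "copy-neutral", which is a claim, not
  an absence).
* **"Variance" cutoff.** The filter uses the unbiased (n−1) sample
  variance; `statistic = "sd"` switches to standard deviation for
  pipelines that meant the other reading.
* **Feature-count selection.** `bestM` is the smallest feature count
  achieving the maximum LOOCV accuracy (parsimony tie-break).
* **Ties in ranking.** Equal Fisher scores are ordered by ascending
  symbol, making ranks a deterministic permutation.
* **Output precision.** TSV/GCT writers render doubles with 17
  significant digits so write-then-read round-trips are exact; diffable
  fixed precision can be had via the `digits` argument.

## The classifier and a scaling pitfall

The default learner is a linear soft-margin SVM (`e1071::svm`,
`cost = 1`) with features standardized to the training mean and SD.
Standardization is not cosmetic here: averaged CNAR features have SDs
far below 1 (noise SD divided by roughly the square root of the
member-probe count), and an unscaled margin penalty then dominates the
hinge loss, collapsing the fit toward a constant majority-class
classifier. In balanced leave-one-out folds the held-out sample's class
is always the training minority, so that collapse is invisible on
separable data (accuracy stays high) but drives permutation-null
accuracy far *below* chance. The standardized default centres the null
near 0.5. Any classifier following the `f(train, labels) -> predict`
contract can be plugged in.

## LOOCV, leakage, and what the null looks like

Per fold, the Fisher ranking and the classifier are recomputed from the
n−1 training samples; the held-out sample influences nothing but its
own prediction. The suite enforces this structurally: corrupting a
held-out sample's values never changes that fold's selected features.

One property of the protocol is worth stating because it is easy to
misread as a bug: under permuted labels, per-fold accuracy indicators
are *positively correlated* — every pair of folds shares all but one
training sample, and per-fold feature selection picks nearly the same
spurious genes — so the distribution of null LOOCV accuracy is
overdispersed relative to a Binomial(n, 0.5). On a 500-gene null cohort
the accuracy SD is roughly twice the binomial value while the mean sits
at chance. Consequently a single permuted-label run lands outside the
central 95% binomial band noticeably more often than 5% of the time;
calibration statements about LOOCV accuracy should use a permutation
reference distribution, not a binomial one.

## What the simulator emulates — and what it does not

`simulationConfig()` defines a two-class cohort with known truth:

* 20 chromosomes × 20 Mb carrying 2,000 genes of 5–20 kb — one gene per
  200 kb, the density of the package's reference layout and close to
  the human genome's; 60 bp probes tiled every 5.5 kb, giving ~37
  member probes per pseudogene under default extension;
* 20 + 20 samples ("short"/"long" survival), 5 driver genes drawn from
  probe-covered genes, alternating gain/loss with a ±1.0 log2-ratio
  class shift on every member probe of the driver's pseudogene,
  i.i.d. Gaussian probe noise (SD 0.3), optional uniform missingness;
* full determinism given a seed.

Gene density matters more than it looks: pseudogene windows are ~212 kb
wide, so at densities much above one gene per ~100 kb, neighboring
genes share most of a driver's member probes and genuinely inherit its
class signal — their Fisher scores then approach the driver's own, as
happens in real data where a CNV region covers several genes. The
defaults keep neighbor leakage modest without hiding the effect.

Features of real aCGH data the simulator deliberately omits: spatially
autocorrelated (wavy) noise, segment-level breakpoints within a window,
GC/mappability artifacts, and survival times (classes are abstract
labels). Passing tests therefore demonstrate the pipeline's contracts
and statistical calibration on clean Gaussian data, not performance on
TCGA-scale cohorts.

## Numerical and degenerate-input choices

* Averaged rows are built as `1/k` exactly; with missing data the
  per-sample mean uses observed members only (`sum/count`), so values
  always lie within the range of observed member probes.
* Zero-probe genes get `k = 0`, an all-zero base-matrix row, and `NA`
  CNAR values — no division by zero, flagged rather than imputed.
* Genes with fewer than two observed values per class score `NA` and
  are placed, unranked, after all ranked genes.
* Consensus entries for sample pairs never drawn together are `NA` with
  a warning; final labels are derived after treating such entries as 0
  similarity.
* Singleton clusters take silhouette 0 by convention
  (`cluster::silhouette` is the computational backend; a from-scratch
  pairwise oracle in the tests pins the values to 1e-12).

## Problem sizes used by the test and acceptance runs

Unit tests run on layouts of tens of genes and a few hundred probes
where brute-force oracles are exact and fast. The end-to-end runs use
the default cohort (2,000 genes, ~72,700 probes, 40 samples) for 100
replicate rankings, a 500-gene cohort for 30–100 permutation-null LOOCV
replicates, and 40-sample two-blob fixtures for clustering checks —
sizes chosen so a complete run takes a few minutes on a single core
while keeping every estimate's Monte-Carlo error well below the margins
being asserted.

## Known limitations

* The fixed 100 kb + 2 kb extension is a blunt instrument; no attempt
  is made to adapt window size per gene.
* A probe may belong to many pseudogenes; no disambiguation beyond
  independent rows is attempted (by design).
* Probe-id reconciliation between base matrix and CNA matrix is exact
  string matching; nothing fuzzy.
* The permutation-null overdispersion described above means LOOCV
  accuracies from small cohorts carry wide uncertainty; prefer the
  permutation reference when quoting significance.
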
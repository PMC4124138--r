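---
title: "Consensus differential expression and weighted-network analysis with consensusNET"
author: "consensusNET authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Consensus differential expression and weighted-network analysis with consensusNET}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(consensusNET)
```

# Scope and scientific setting

`consensusNET` re-implements, as a reusable and fully tested pipeline, an
integrated network-based analysis of two-group expression microarray
studies. The motivating application is the transcriptome of small
intestinal neuroendocrine tumors (NETs) compared with normal intestinal
mucosa: small cohorts (around 9 tumors versus 3 controls per dataset),
strong secretory biology, and the need to combine evidence across several
ranking statistics and across independent datasets before trusting any
single gene call.

The pipeline runs in six stages:

1. **Quality control** — detection-call probe filtering, whole-array
   outlier detection, quantile normalization, probe-to-gene collapsing.
2. **Consensus differential expression** — five rankers (fold change,
   ordinary t, shrinkage t, moderated t, SAM) combined by intersection.
3. **Functional enrichment** — hypergeometric over-representation and a
   Bayesian model-based gene-set activation model.
4. **Network analysis** — mapping consensus genes onto a protein–protein
   interaction network as seeds, extracting the maximum-weight
   shortest-path subnetwork, community detection and community comparison.
5. **Cross-dataset co-analysis** — fold-change correlation, shared DE
   genes, ranking overlap, curated-list intersections.
6. **qPCR validation statistics** — ΔΔCT quantification against a
   housekeeping gene with nonparametric group tests.

Every stage can be exercised on synthetic data with planted truth
(`simulateStudy()`), which is how the package tests itself end to end
without any external download.

# Quality control and normalization

**Detection filtering.** A probe is retained when its present-call count is
*strictly greater* than half of the arrays (`filterByDetection()`,
`minFraction = 0.5`). The strict inequality matters for even sample counts:
a probe present in exactly 6 of 12 arrays is dropped.

**Array outliers.** Each array is scored by the Kolmogorov–Smirnov
statistic `D` between its intensity distribution and the pooled
distribution of all arrays — including the array under test, the simplest
reading of "pooled" (`ksOutlierDetection()`). Both empirical CDFs jump only
at pooled data points, so the supremum is evaluated exactly there; ties are
handled through the pooled counts. No fixed numeric cutoff is defensible
across cohort sizes, so arrays are flagged by the parameter-free Tukey
upper fence `Q3 + 1.5 IQR` of the `D` values, the convention of common
array-QC practice.

Two consequences of this design deserve emphasis. First, outlier scoring
**must precede quantile normalization**: normalization forces identical
column distributions, after which every `D` is exactly zero. The pipeline
therefore scores outliers on the filtered, unnormalized intensities (the KS
statistic is invariant under the monotone log2 transform, so linear or log
scale makes no difference). Second, with a small unbalanced design, the
minority group can drift away from the pooled distribution when many genes
are genuinely differentially expressed, and the fence may flag healthy
minority-group arrays. `runPipeline()`/`analyzeStudy()` therefore refuse to
drop flagged arrays when that would leave a group with fewer than two
members; the flags are still reported.

**Normalization.** Intensities are transformed as `log2(x + 1)` and
quantile-normalized: each column's sorted values are replaced by the
across-column means of the order statistics, so all columns share one value
multiset; ties within a column receive the mean of the reference values at
their ranks (`quantileNormalize()`). This is the quantile/log2 core of the
RMA pipeline; the probe-level background-correction convolution model is
out of scope because the pipeline's entry point is an intensity matrix, not
CEL files.

**Collapsing.** Probes without a gene mapping are removed; multiple probes
of one gene are averaged arithmetically on the log2 scale, after
normalization, matching the order of operations of standard microarray
re-annotation (`collapseProbesToGenes()`).

# Consensus differential expression

All statistics compare tumor against normal on gene-level log2 values and
share the numerator `r = mean(tumor) − mean(normal)`.

* **Fold-change ranker** — a gene passes when `|log2FC| ≥ fcThreshold`
  (default 1, the conventional two-fold cutoff). The signed linear fold
  change is presented as `+2^x` for `x ≥ 0`, `−2^(−x)` otherwise.
* **Ordinary t** — pooled-variance two-sample t with `n1 + n2 − 2` df.
* **Shrinkage t** — per-gene pooled variances shrunk toward their median
  with an adaptive weight `λ = min(1, Σ Var̂(v_g) / Σ (v_g − v_med)²)`,
  where `Var̂(v_g)` is the standard unbiased estimate of the sampling
  variance of each group's variance, pooled across groups. P-values use the
  t distribution with `n1 + n2 − 2` df; this is an approximation (the exact
  null of a shrunken denominator is not t) and is documented as such.
* **Moderated t** — empirical-Bayes variance squeezing
  `s²_post = (d0 s0² + df s²)/(d0 + df)` with the prior df `d0` and scale
  `s0²` from moment matching on `log s²` (trigamma inversion), delegated to
  `limma::squeezeVar`; `d0 = ∞` degenerates to the common-variance normal
  limit, `d0 = 0` reproduces the ordinary t exactly.
* **SAM** — `d = r/(s + s0)` with `s` the pooled standard error and the
  fudge factor `s0` selected among the 0, 5, …, 100th percentiles of `s` to
  minimize the coefficient of variation of `mad(d)` across up to 100
  quantile windows of `s`. Significance comes from label permutations:
  `nPermutations` (default 1000) label reassignments drawn *distinct from
  the observed labelling*, two-sided, with a +1 pseudo-count in numerator
  and denominator. Excluding the observed labelling keeps the attainable
  p floor at `1/(B + 1)` even for designs with few distinct splits (a 9v3
  design has only 220), which is what makes permutation p-values usable
  under BH at small sample sizes. When fewer than 20 distinct splits exist,
  all of them are enumerated instead and the pseudo-count is dropped.
  Degenerate genes (zero spread and zero difference, which quantile
  normalization can produce) are mapped to `d = 0`.

Each statistic's p-values are Benjamini–Hochberg adjusted
(`stats::p.adjust`). A gene is a **consensus call** when it is significant
under at least `mRequired` of the five methods (default 5, the full
intersection — the strictest reading of "consistently identified by
multiple ranking algorithms") *and* the four statistics agree in sign. The
headline adjusted p per gene is the maximum over the four statistics, i.e.
the most conservative of the agreeing methods.

At the default design conditions (2000 genes, 5% DE at `|log2FC| = 2`,
noise SD 0.5, 9v3), the consensus call attains mean sensitivity above 0.9
with empirical FDR well below 0.1, and makes essentially no calls when no
effect is planted; both properties are checked by the test suite across 20
seeded replicates.

# Functional enrichment

**Hypergeometric over-representation.** For each term, the upper-tail
probability `P(X ≥ k)` of `k` DE genes among the term's `K` universe genes
(`n` DE genes of `N`). Terms with fewer than 10 genes in the universe are
excluded before testing (`minSize = 10`) — small terms produce unstable
enrichments. BH adjustment is applied *within* each namespace
(BP/CC/MF/pathway/secretory) because namespaces are enriched separately.
The graph-decorrelation variants of GO testing (elim/weight) are out of
scope; this is the classic Fisher-style test.

**Model-based gene-set activation (`mgsa()`).** Each set carries a hidden
Bernoulli activation with prior `π` (default 0.05); a gene is hidden-on iff
it belongs to an active set; the observed DE label arises with
false-positive rate `α` (default 0.1) and false-negative rate `β` (default
0.25). The posterior activation probability per set explains the DE list
jointly rather than term-by-term, which penalizes redundant overlapping
sets. Posteriors are computed by exact enumeration of all `2^S` activation
states when `S ≤ 20` and otherwise by a Metropolis sampler toggling one
random set per sweep (default `1e5` sweeps, 10% burn-in, seeded). The
sampler tracks the exact enumeration to within 0.05 on 5–10-set problems in
the test suite.

**Overlap of enrichment results.** The published style of "X% overlap"
between two datasets' enriched pathways has an ambiguous denominator; both
`|A∩B| / min(|A|,|B|)` (headline) and the Jaccard coefficient are reported.

# Network analysis

Nodes of the interaction network are weighted `w = −log10(p)` using each
gene's headline *adjusted* p-value (the raw/adjusted choice is exposed via
`pColumn`; adjusted is the default because the weights should reflect the
evidence that survives multiplicity). Unmapped nodes get weight 0;
consensus genes become **seed nodes**.

For every unordered seed pair in the same component,
`maxWeightShortestPath()` finds, among all minimum-hop paths, one
maximizing the sum of node weights (both endpoints included), by dynamic
programming over the breadth-first layered graph. "Shortest" is hop count
because the model weights nodes, not edges; remaining ties break to the
lexicographically smallest node sequence, making results fully
deterministic. One path is kept per pair (the maximal one). Seed pairs in
different components are skipped and reported, not errors — real
interactomes are disconnected. The union of the selected paths' nodes and
consecutive edges is the extracted subnetwork; non-seed nodes on selected
paths are **linkers**.

Communities are found by greedy agglomerative modularity maximization:
starting from singletons, repeatedly merge the community pair with the
largest gain `ΔQ = 2(e_ij − a_i a_j)` until no merge has positive gain,
with ties broken to the smallest community identifiers. `Q = Σ_c (e_c/m −
(d_c/2m)²)`. The greedy optimizer was chosen over stochastic methods so
tests are deterministic; on canonical cases (two disconnected triangles,
complete graphs) it provably attains the brute-force optimum, which the
test suite verifies by enumerating all partitions. Community similarity
across two partitions is the Jaccard coefficient per community pair — 0 for
disparate and 1 for identical communities.

`secretorySubnetwork()` selects subnetwork nodes annotated to a list of
terms — by default the serotonin-metabolism (GO:0042428, GO:0042427,
GO:0007210, GO:0004993), substance-P-signaling (GO:0071861, GO:0007217) and
secretion (GO:0007218, GO:0030141) terms — plus their direct neighbors,
labeling each node `annotated` or `neighbor`.

# Cross-dataset co-analysis

`correlateFoldChanges()` computes the Pearson correlation (Spearman
available) of log2 fold changes over the common gene universe with the
parametric two-sided p. `sharedDEGenes()` intersects the consensus sets and
reports both the min-based fraction (headline) and Jaccard.
`topkJaccard()` compares the top-k genes (default 1000) ranked by headline
adjusted p, ties broken by `|log2FC|` descending then gene id.
`intersectCuratedList()` matches consensus genes of a chosen direction
against user-supplied symbol lists (e.g. cancer-census genes or
enteroendocrine transcription factors), case-insensitively after whitespace
stripping; ortholog mapping is the user's input preparation.

# qPCR validation

`ddctFoldChange()` implements the Livak ΔΔCT method: `ΔCT = CT_target −
CT_housekeeping` per sample, centered on the arithmetic mean ΔCT of the
normal group, `FC = 2^(−ΔΔCT)`. By construction the normal group's fold
changes have geometric mean 1, and the estimate is invariant to per-sample
constant CT shifts. Fold changes are summarized as mean ± SEM on the linear
scale. `groupCompare()` tests tumor against normal with a two-sided
Mann–Whitney test — exact by enumeration of all `C(n1+n2, n1)` label
assignments when both groups have ≤ 8 samples (ties handled exactly:
`U` counts strict wins plus half-ties), the normal approximation with tie
correction otherwise — plus optional Spearman correlation against a
covariate and Fisher's exact test on a user-supplied 2×2 table.

# The synthetic-data generator

`simulateStudy()` generates all pipeline inputs from one `simConfig()`,
with an RNG stream per artifact (expression, network, gene sets, qPCR)
derived from the master seed, so regenerating one artifact never perturbs
the others. Identical configurations produce byte-identical outputs.

* **Expression** — per-probe intensities
  `2^(N(baselineLog2Mean, baselineLog2Sd) + effect + N(0, noiseSd))`:
  log2-scale Gaussians exponentiated to the linear scale, so the pipeline's
  log2 transform is their exact inverse and group-mean expectations are
  closed-form. Planted DE genes (fraction `deFraction`, default 5%) shift
  tumor samples by ±`deLog2FC` (default 2, split evenly up/down). Each gene
  receives 1–3 probes (probabilities 0.5/0.3/0.2, echoing the roughly
  1.5–2 probes per gene of the emulated array generations); 5% of probes
  are unmappable, exercising the "no gene record → removed" rule. A
  `backgroundFraction` (default 0.3) of probes — always including the
  unmappable ones, never probes of planted genes — sits 3 log2 units below
  baseline and receives present calls at `detectProbBackground = 0.3`
  versus `detectProbExpressed = 0.9`, so the >50% detection rule removes
  most background probes at the default 12-array design. Optional outlier
  arrays are shifted wholesale by `outlierShift` log2 units.
* **Network** — a preferential-attachment graph (`ppiNodes = 300`,
  `ppiEdgesPerNode = 3` at desk scale) in which `plantedModuleSize = 20`
  vertices are rewired into a connected subgraph (random spanning tree plus
  extra edges) and labeled with planted DE genes.
* **Gene sets** — `nGeneSets = 50` sets of 10–50 genes; designated enriched
  sets and the eight fixed secretory GO terms oversample planted DE genes
  at `geneSetDEOdds = 10`. Undersized sets are emitted as-is — filtering is
  the enrichment stage's job.
* **qPCR** — `CT = CT_base − log2(relative expression) + N(0, qpcrSigma)`
  with the housekeeping gene (default `ALG9`) constant in expectation, 13
  tumor and 8 normal samples by default (the size of a typical independent
  validation cohort). At `qpcrSigma = 0` the ΔΔCT round trip is exact.

The defaults are the study conditions of the emulated design: 9 tumor vs 3
normal arrays, 2000 genes at desk scale. The generator deliberately does
**not** model probe-level chemistry, batch effects beyond a whole-array
shift, correlated gene-gene noise, or heavy-tailed intensity distributions.
Passing tests on these data therefore demonstrate the correctness of the
algorithms and their calibration under the stated noise model — not
robustness to the full messiness of real arrays, where normalization
choices and annotation versions dominate.

# Numerical choices and degenerate inputs

* Zero within-group variance: ordinary t maps to ±∞ with p = 0 (warning);
  0/0 genes map to statistic 0, p = 1.
* Fewer than 3 genes: the shrinkage target is ill-defined; falls back to
  the ordinary t with a warning. Fewer than ~5 genes per variance window:
  the SAM fudge-factor search falls back to the median spread.
* Non-finite moment estimates in the moderated t: `d0 = ∞` limit (handled
  inside `limma::squeezeVar`).
* Single-sample matrices: quantile normalization returns the log2 values
  unchanged with a warning.
* All tie-breaks (path choice, community merges, rankings) are
  deterministic and documented at the function level; every stochastic
  component takes an explicit seed.

# Problem sizes used by the tests

The test suite and the acceptance script run entirely on simulated data:
2000-gene studies for parameter recovery (20 and 10 seeded replicates
respectively), 300-gene studies for fast module-level checks, graphs of at
most 12 nodes against exhaustive path enumeration (100 instances), all 203
partitions of 6 nodes for the modularity brute force, `2^S` enumeration for
set-activation models up to S = 10 against `1e5`-sweep MCMC runs. These
sizes were chosen so each oracle is exactly computable while the pipeline
still operates in its intended regime.

# Known limitations

* The shrinkage-t p-value uses a t reference distribution; calibration is
  approximate by construction and the consensus rule treats it as one vote
  among five.
* The SAM permutation null is per-gene, not pooled across genes; with very
  few distinct label splits the exact-enumeration p floor is coarse.
* The greedy modularity optimizer inherits the resolution limit of
  modularity and can merge small communities attached to hubs.
* Enrichment ignores the GO graph structure (no true-path propagation).
* Reproducing any specific published cohort's numbers requires that
  cohort's original intensity matrices and its era's probe annotation; the
  package's claims are calibration and recovery on its own generative
  model.
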
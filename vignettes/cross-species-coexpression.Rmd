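---
title: "Comparing developmental expression programs across two species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing developmental expression programs across two species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(orthodev)
```

## The problem

Two related species can pass through morphologically indistinguishable
embryonic stages while running substantially different transcriptional
programs — the phenomenon known as developmental system drift. Detecting it
requires comparing, gene by gene and module by module, *when* homologous
genes are deployed during development in each species. `orthodev` implements
that comparison for a design of two species sampled at three consecutive
stages — blastula ("prawn chip", PC), gastrula (G) and early larva
("sphere", S) — with three biological replicates each, the design typical of
coral (*Acropora*) embryonic RNA-seq studies.

The pipeline is: per-species differential expression between consecutive
stages, K-means coexpression clustering of the differentially expressed
genes (DEGs) into six stage archetypes, then cross-species statistics over
orthologs (shared/exclusive DE, stage synchrony, archetype overlap,
gastrula-up core modules), in-paralog divergence classes, bait-gene
correlation networks, and hypergeometric term enrichment. A synthetic data
generator with full ground truth stands in for raw sequencing data, so every
estimator can be validated by parameter recovery.

## The model behind the synthetic generator

Counts for gene $g$ in sample $s$ are negative binomial,

$$K_{gs} \sim \mathrm{NB}\!\left(\mu_{gs},\ \alpha\right), \qquad
  \mu_{gs} = \mu_g \cdot 2^{\beta\, u_g(\mathrm{stage}(s))} \cdot f_s,$$

with a log-normal baseline $\mu_g$, a single shared dispersion $\alpha$
(default 0.05, a typical bulk RNA-seq replicate dispersion), a planted
up-state log2 fold change $\beta$ (default 2), and per-sample size factors
$f_s$ drawn log-uniform in $[0.7, 1.4]$. The up-indicator $u_g$ comes from
the gene's **archetype**: one of six binary stage patterns — C1 up in PC, C2
in PC+G, C3 in G, C4 in G+S, C5 in S, C6 in PC+S — or `flat` (no
regulation). A single shared dispersion is deliberate: it is exactly the
model the differential-expression module assumes, which makes
parameter-recovery tests well-posed.

Homology structure is drawn per orthogroup from a relationship-class mix
(defaults 86% one-to-one, 10% one-to-many toward species A, 2% toward
species B, 2% many-to-many, the proportions reported for *Acropora*
proteome comparisons). Conservation is planted at the pair level: a
one-to-one ortholog pair shares its archetype with probability
`conserved_fraction_orthologs` (default 0.13); in-paralog pairs use
per-species fractions (defaults 0.47 and 0.83, mirroring the strongly
asymmetric paralog conservation reported for the two coral species).

Two design points of the planting scheme matter for interpretation:

* **Flat status is shared within a pair.** If the lead gene is flat its
  partner is flat too, and a *non-conserved* partner of a non-flat gene
  draws a different **non-flat** archetype. This is the only scheme under
  which the measured same-archetype fraction among both-non-flat pairs is
  an unbiased estimate of the planted fraction; if divergent partners could
  fall back to flat, the conditional fraction would be inflated.
* **Members of one-to-many and many-to-many groups draw archetypes
  independently**; conservation is only planted (and only recovered) for
  one-to-one pairs, which is also the subset all cross-species statistics
  use.

What the generator does *not* emulate: per-gene dispersion heterogeneity,
expression-dependent dispersion trends, correlated genes outside the
planted archetypes, library-composition biases beyond scalar size factors,
and any sequence-level effects (mappability, length biases beyond the TPM
length term). Passing recovery tests therefore demonstrates correctness of
the estimators under the stated model, not robustness to every artifact of
real libraries.

## Normalization choices

* **TPM** follows the standard rate normalization
  ($10^6 \cdot$ rate / total rate, rate = count per kilobase); transcript
  lengths are log-uniform in 500–5000 nt in the generator and only matter
  here.
* **Size factors** are median-of-ratios: the median over genes with a
  positive geometric mean of the count-to-geometric-mean ratio. The plain
  ratio median is used (not the exponentiated median of log ratios), which
  matches the formula as stated and differs from it only at even gene
  counts, where the median interpolates.
* **The variance-stabilizing transform** is `log2(count / factor + 1)` — a
  dependency-free monotone stand-in for parametric VST. It anchors zeros at
  0 and flattens the NB mean–variance trend at the expression levels that
  drive clustering; it does not reproduce a parametric VST's behavior for
  near-zero counts.

## Differential expression

The test is a closed-form Wald test rather than a GLM fit: per gene,
$\mathrm{LFC} = \log_2\frac{\bar m_L + 0.5}{\bar m_E + 0.5}$ on
size-factor-normalized group means (later stage over earlier, so positive
means up later), with the delta-method standard error under
$\mathrm{Var}(\bar m) = (\bar m + \alpha \bar m^2)/n$. Dispersion
$\alpha_g$ is method-of-moments on normalized counts with stage means
removed, floored at $10^{-8}$ and shrunk halfway (log scale) toward the
across-gene median — a deliberately simple stand-in for empirical-Bayes
shrinkage. A gene is a DEG when $|\mathrm{LFC}| \ge 1$ and BH-adjusted
$p < 0.05$; the boundary convention is configurable (`boundary = "gt"`
gives $>1$, $\le 0.05$) because published descriptions of this threshold
vary in boundary inclusion. Genes with all-zero counts in both groups are
kept with $p = 1$ so result tables stay aligned with the count matrix.

The +0.5 pseudocount bounds the LFC of genes observed in only one group and
makes the statistic defined everywhere; its cost is shrinkage of very large
fold changes at low counts, which is irrelevant at the default effect size.
No outlier handling, independent filtering or LFC shrinkage is performed.

## Clustering and archetype labels

Clustering input is the per-gene standardized VST over all nine samples of a
species (replicate-level, not stage means — stage means are available but
three points per gene would discard the replicate structure). Zero-variance
genes are flagged and excluded. K-means uses k-means++ seeding with 10
restarts, keeping the best within-SS fit; it is deterministic given the
seed. `stats::kmeans` performs the iterations; if a restart yields an empty
cluster it is retried with a fresh k-means++ draw (rather than re-seeding
the single empty centroid), a difference visible only in pathological
configurations. The one-point-per-cluster boundary case is returned exactly.

The cluster count is fixed at six by design; `elbow_curve()` documents the
choice. Its suggested k maximizes the second difference of the **log**
within-SS curve: the raw second difference is dominated by the large early
absolute drops and points at k = 2–3 even for six well-separated planted
groups, whereas relative curvature collapses exactly where the planted
structure is exhausted.

Cluster-to-archetype labelling z-scores each centroid's three stage means
and each archetype template, scores all pairs by cosine similarity, and
takes the bijection maximizing total similarity by exhaustive search over
the 720 permutations (optimal matching, not greedy; ties resolve to the
first optimum in lowest-cluster-index order).

## Cross-species statistics

All ortholog statistics run on one-to-one pairs. "DEG" at the species level
means the union of DEGs over both comparisons. "Up-regulated at G" means an
up-stage of G in either comparison — the G side of PC-vs-G or of G-vs-S.
Synchrony percentages are reported to the nearest integer and overlap and
composition percentages to one or two decimals, matching how such tables
are conventionally printed. In the archetype-overlap table the denominator
is all both-DE pairs; pairs with an unclustered member are counted in the
denominator but reported separately from the 6×6 matrix, so the
same-archetype percent is conservative with respect to clustering dropouts.

For paralogs, P1/P2/P3 classify pairs by whether both, one or neither gene
is a DEG in a comparison, and Pk1/Pk2/Pk3 by cluster membership. "Similar
expression" is operationalized as identical up-stage (P1) or identical
archetype (Pk1). Pair correlations are Pearson over the nine replicate-level
VST values — three stage means would make correlations nearly degenerate —
and pairs with an undefined correlation (zero variance) are excluded from
the high-correlation fraction's denominator. The pipeline reports that
fraction over Pk1 pairs, the subset for which co-clustering makes the
comparison meaningful.

## Correlation networks

A bait network connects a query gene to every gene whose Pearson
correlation with it is at or beyond the cutoffs. Cutoffs are empirical
quantiles of the bait's correlation distribution (defaults: 5th and 95th
percentile, linear interpolation between order statistics so results are
bit-reproducible), or an absolute mode `|r| >= t` (default 0.8) matching
how published figure networks are typically thresholded; both modes exist
because tool defaults and figure legends rarely agree. Correlations are
computed within species only; cross-species comparison happens at the
homolog-family level, where partners sharing an orthogroup share a family
and each family gets a per-network sign (positive, negative, or mixed when
its partners disagree). Concordance requires the same non-mixed sign in
both networks. At least 20 finite correlations are required before
quantile cutoffs are computed.

## Enrichment

Over-representation is the exact hypergeometric upper tail with BH
adjustment. Term sets are flat — no ontology-hierarchy propagation — and
the reference population defaults to all genes with at least one
annotation. Terms absent from the query are not tested, which fixes the BH
denominator at the number of observed terms; both choices are stated
because they change adjusted p-values. The generator plants one enriched
term by multiplying its sampling weight (default ×4) for genes of the
gastrula-only archetype C3.

## Numerical and degenerate-input conventions

* BH adjustment validates its input and is order-invariant; it is *not*
  idempotent (re-adjusting adjusted values collapses them toward the
  largest), so no such property is asserted anywhere.
* Quartile tables split expressed transcripts (stage-mean TPM > 0) at the
  pooled 25/50/75 ranks, ties broken by stable row order; bins differ in
  size by at most one. The chi-square goodness-of-fit against uniform
  (df = 3, no continuity correction) is slightly conservative under the
  null because class bin counts are hypergeometric, not multinomial — the
  calibration test budgets for ≤ 7% rejections at α = 0.05 accordingly.
  Whether published quartile analyses bin per class or pooled is usually
  unstated; pooled binning is used here so "Q4" always means the top
  quarter of all expressed transcripts.
* All randomness flows from one root seed through fixed per-stage
  substreams, so any stage can be regenerated independently and the whole
  pipeline is checksum-reproducible.

## Problem sizes

The default synthetic study uses 3,000 orthogroups (≈ 3,900–4,400 genes
per species including one-to-many members and dedicated paralog genes),
500 and 200 in-paralog pairs for the two species, and three replicates of
three stages. These sizes were chosen as the smallest at which the
recovery statistics stabilize: DE sensitivity and archetype accuracy
≈ 0.99+, recovered ortholog conservation within ±0.02 of the planted 0.13,
and Pk1 same-archetype fractions within ±0.05 of the planted values. Unit
and property tests use smaller fixtures (60–500 elements) with brute-force
oracles.

```{r quick-run}
cfg <- synth_config(seed = 7, n_orthogroups = 300,
                    n_paralog_pairs = c(60, 40))
res <- run_pipeline(cfg)
res
res$report$synchrony_percent
res$report$cluster_overlap_percent
```

## Known limitations

* The Wald-on-means DE test and the log VST are transparent stand-ins, not
  re-implementations of a GLM-based pipeline; absolute DEG counts on real
  data would differ from a GLM even when the planted-truth operating
  characteristics are excellent.
* A single shared dispersion in the generator means dispersion-estimation
  shrinkage is never stress-tested against heavy per-gene heterogeneity.
* Orthology is consumed, never inferred: the groups-file parser trusts its
  input, and relationship classes follow from member counts alone.
* Network comparison reduces each family to one sign per network; a family
  with internally mixed signs is never counted concordant, which is
  conservative for rewiring claims.
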
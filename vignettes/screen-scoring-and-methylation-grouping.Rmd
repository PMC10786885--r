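---
title: "Scoring dual-condition CRISPRi screens and grouping tumors by methylation"
author: "screenmeth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring dual-condition CRISPRi screens and grouping tumors by methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(screenmeth)
```

# Overview

`screenmeth` implements two analyses that recur in functional-genomic studies
of Schwann cell tumors and similar systems:

1. **Screen scoring.** A pooled dual-sgRNA CRISPRi screen is run under two
   conditions — vehicle and drug (for instance a MEK inhibitor) — against a
   shared post-transduction baseline (T0). The pipeline turns construct
   counts into doubling-normalized, NTC-standardized phenotype scores and
   classifies each construct as a shared or condition-selective
   enriched/depleted hit.
2. **Methylation grouping.** Tumor samples profiled on a methylation array
   are grouped from their beta values by probe filtering, variable-probe
   selection, Spearman-correlation-distance consensus k-means over sample
   resamples, and a CDF/silhouette choice of the number of groups.

A seeded synthetic-data module generates both input types with known planted
truth, so every stage of both pipelines is exercised and verified at desk
scale.

# The screen scoring model

## From counts to phenotypes

Counts are first equalized across samples by subsampling each sample column
without replacement (multivariate hypergeometric) to the minimum column
total; this mirrors read downsampling and, unlike rescaling, preserves the
count nature of the data. Constructs with a mean count below 50 normalized
reads across all samples are removed: below that depth the log2 ratios are
dominated by shot noise.

For construct $i$, arm $a$ and T10 replicate $r$, with a pseudocount $c = 1$
(configurable; the pseudocount bounds ratios at zero counts),

$$L_{iar} = \log_2\frac{n^{T10}_{iar} + c}{n^{T0}_{i} + c}.$$

The per-arm **phenotype** centers the replicate-mean ratio
$\bar L_{ia}$ on the median of the non-targeting controls and scales it by
the arm's population doublings $D_a$:

$$\text{phen}_{ia} = \frac{\bar L_{ia} -
  \operatorname{median}_{j \in \mathrm{NTC}} \bar L_{ja}}{D_a},
\qquad
z_{ia} = \frac{\text{phen}_{ia}}{\operatorname{sd}_{j \in \mathrm{NTC}}
  (\text{phen}_{ja})}.$$

The order of operations — center first, then divide by doublings, then
standardize on the per-doubling NTC spread — makes the NTC median phenotype
exactly zero and the z score unit-free; a z of 3 means a growth-rate effect
three NTC standard deviations from null, per doubling. Both normalizations
are stated by the procedure this package implements; the order is a design
choice of this package. The realized doubling counts of a screen are a
required user input (defaults 8 for vehicle, 6 for the drug arm in the
simulations) and are carried in the result metadata, since phenotypes are
only comparable across screens at known $D$.

At least 10 NTC constructs must survive filtering; with fewer, the centering
and the spread estimate are too unstable, and the pipeline refuses to score
(`min_ntc` is exposed so that deliberately tiny worked examples can run).

## Significance: a per-construct negative-binomial Wald test

Per arm, each construct's counts are modeled as negative binomial with a
log-linear mean and a T10 indicator; size factors are all 1 after depth
equalization. Because the model is saturated in the two groups, the
maximum-likelihood group means are the sample means (a half count is added
per group so zero-count groups stay defined), and the Wald statistic is the
log mean ratio over its standard error from the observed Fisher information:

$$W_i = \frac{\log(\hat\mu_{i,T10}/\hat\mu_{i,T0})}
  {\sqrt{\frac{1+\alpha_i\hat\mu_{i,T0}}{n_0\hat\mu_{i,T0}} +
         \frac{1+\alpha_i\hat\mu_{i,T10}}{n_1\hat\mu_{i,T10}}}},$$

with a standard normal reference and two-sided p-values, adjusted by
Benjamini–Hochberg across tested constructs (standard step-up with the
cumulative minimum handling ties).

The dispersion $\alpha_i$ is estimated by method of moments within replicate
groups (only groups with two or more replicates contribute), then shrunk
50/50 toward a mean–dispersion trend $\alpha(\mu) = a_0 + a_1/\mu$ fitted by
least squares across all constructs with one outlier-trimming pass and
coefficients floored at zero. The shrinkage stabilizes the very noisy
two-degree-of-freedom per-construct estimates while letting genuinely
overdispersed constructs keep wider intervals. Under the all-null
simulation, the empirical type-I error of this test at $p < 0.05$ sits
within [0.03, 0.07] (checked in the test suite).

This test is self-contained by design. Published screens often use a
packaged Wald implementation whose internals (dispersion shrinkage,
filtering, outlier handling) differ in detail; exact numerical agreement
with any particular package is not a goal, and the hit *classes* rather
than raw p-values are the stable interface.

## Hit classification

With significance defined as $\text{padj} < \alpha$ (default 0.05) and
direction as the sign of the arm's mean log2 fold change:

* significant in both arms, same direction → `shared_enriched` /
  `shared_depleted`;
* significant in the drug arm only → `drug_selective_enriched` /
  `drug_selective_depleted`;
* significant in the vehicle arm only → `vehicle_only_*`;
* otherwise `not_significant`.

Significance in both arms with opposite directions is not covered by the
published class set; it is classified here as drug-selective in the drug
arm's direction, on the grounds that the drug response opposes and therefore
dominates the fitness response. The case is rare (it requires a strong
fitness effect that reverses under drug).

As quality control, constructs targeting core essential genes should be
overwhelmingly depleted in the vehicle arm; `qcEssentialDepletion()` counts
significant depletions and enrichments in an essential set and passes when
depleted constructs outnumber enriched ones more than tenfold.

## Worked example

```{r screen-example}
sim <- simulateScreen(ScreenSimConfig(seed = 7))
res <- scoreScreen(sim$experiment)
table(res$hit_class)
```

The planted composition (10% essential, 2% fitness suppressors, 1%
resistance, 1% sensitizer genes among 2000 genes plus 100 NTC pairs) is
recovered: resistance genes appear as `drug_selective_enriched`, sensitizers
as `drug_selective_depleted`, essentials as `shared_depleted`.

# The synthetic screen generator

The generator defines the study conditions under which the pipeline is
verified:

* one dual-guide construct per gene (2000 genes at desk scale, with a
  genome-scale preset of 23,483 genes plus 1137 NTC pairs matching the
  published library composition);
* baseline abundances $a_i \sim \mathrm{LogNormal}(0, 0.5)$, emulating
  uneven library representation;
* expected T10 abundance $\propto a_i\,2^{D_a(\gamma_i + \rho_i\,[a =
  \text{drug}])}$, where $\gamma$ is the per-doubling growth effect (−0.3
  for essentials, +0.2 for fitness suppressors) and $\rho$ the drug-arm-only
  effect (+0.5 for resistance, −0.5 for sensitizer genes);
* counts per sample drawn Dirichlet-multinomial: a relative-abundance vector
  from a Dirichlet with concentration `overdispersion` × (expected abundance
  scaled to mean 1), then a multinomial at total depth
  `n_constructs × depth_per_construct`. Column totals are therefore exact by
  construction, which keeps downsampling tests sharp.

Scaling the Dirichlet concentration per *mean-relative* abundance makes the
marginal overdispersion of each construct approximately negative binomial
with dispersion $1/\text{overdispersion}$, independent of library size — so
`overdispersion = 1000` means a 0.1% excess coefficient of variation
squared, a realistic figure for a well-executed pooled screen, and the same
noise level whether 2000 or 23,483 genes are simulated. (Scaling the
concentration on the simplex instead would make the noise explode with
library size and would drown the planted effects at any realistic depth.)

The generator does not simulate sequencing errors, PCR jackpotting, or
guide-level heterogeneity within a construct; passing recovery tests
demonstrates that the scoring mathematics is correct under the stated noise
model, not that any particular wet-lab screen meets that model.

# The methylation grouping model

## Probe filtering and selection

Probes are removed if they map to chrX/chrY (sex confounding), overlap a
common SNP at or adjacent to the interrogated CpG, fail to map uniquely, or
have a detection p-value ≥ 0.05 in *any* sample; the removal tally
attributes each probe to the first matching rule in that order. Among
retained probes, the top `n` by standard deviation of beta across samples
are clustered (ties broken by probe id so selection is deterministic). The
consensus run uses the top 10,000 by default — the middle of the
1000/10,000/15,000 robustness sweep — while the hierarchical cross-check
uses 5,000.

Beta values (not M-values) are clustered: they are bounded, bimodal and
far from normal, which is exactly why a rank-based distance is used.

## Consensus k-means in Spearman geometry

The distance between samples is $d(i,j) = 1 - \rho_{\mathrm{Spearman}}$
across the selected probes. k-means needs a coordinate space, so each
sample is rank-transformed across the probes and k-means is run on the rank
vectors: squared Euclidean distance between whole-probe rank vectors is a
fixed affine function of the Spearman correlation, so k-means on ranks is
k-means in Spearman geometry. Computationally, the rank matrix is first
embedded by an exact (untruncated) singular-value decomposition; this
preserves every pairwise Euclidean distance and hence the k-means
objective, while reducing each sample from 10,000 rank coordinates to at
most n−1, which is what makes 7000 resampled k-means runs take about a
minute instead of hours.

For each k in 2..8 and each of 1000 resamples, 80% of samples are drawn
without replacement and clustered by k-means (k-means++ initialization, 10
restarts, best total within-cluster sum of squares kept, all seeded). The
consensus entry M(k)[i,j] is the fraction of co-sampled resamples in which
i and j co-clustered. Per-k labels come from average-linkage hierarchical
clustering of 1 − M(k) — deterministic, standard consensus-clustering
practice — with group ids canonicalized by decreasing cluster size.

## Choosing the number of groups

Two diagnostics are computed per k: the empirical CDF of the
upper-triangle consensus entries with its trapezoid area A(k) and relative
increment Δ(k), and the mean silhouette width of the consensus partition on
the Spearman distance of the clustered data. **The selected k maximizes the
mean silhouette, ties to the smallest k**; the CDF area curve is reported
as the corroborating stability diagnostic, with the smallest k past which
every relative gain stays below `auc_gain_threshold` (default 0.10)
annotated in the parameters.

The silhouette is deliberately taken on the data distance rather than on
1 − M(k). A perfectly resampling-stable partition has a consensus matrix of
pure 0/1 and hence a consensus-distance silhouette of exactly 1 — and in
lopsided cohorts *both* a merged and a split partition can be perfectly
stable (merging the two smallest of three well-separated groups is
stable at k = 2), so the consensus-distance silhouette cannot rank
candidate k at all. The data-distance silhouette measures what "loss of
coherence beyond k" means: whether the cut points still separate samples
that are far apart in the methylation data. On the default cohort it peaks
sharply at the planted number of groups, and it is what makes the selection
robust to the variable-probe count.

The Δ(k) curve alone is also not a reliable selector on clean synthetic
data: splitting a tight homogeneous group beyond the true k produces
*unstable* cuts, whose fractional consensus values add substantial CDF area
(a large Δ just past the true k), the opposite of the saturation heuristic
assumes. On real cohorts with internal substructure the curve behaves more
gently; the package reports it for exactly that corroborating use.

## Worked example

```{r meth-example, eval = FALSE}
sim <- simulateMethylation(MethSimConfig(seed = 1))   # 25/8/86 cohort
se  <- filterProbes(sim$experiment)                   # 17800 probes remain
sel <- selectVariableProbes(se, 10000)
res <- evaluateK(consensusCluster(sel, k_range = 2:8,
                                  n_resamples = 1000, seed = 1))
kDiagnostics(res)
selectedK(res)        # 3
head(assignGroups(res))
```

(Not evaluated here: the full 1000-resample run takes about 90 seconds; the
test suite runs it.)

# The synthetic methylation generator

The default cohort plants three groups of 25, 8 and 86 samples (119 total,
mirroring a three-group tumor cohort with one dominant benign group). Each
group owns 500 informative probes whose mean beta differs by 0.4 between
the group and the rest; uninformative probes draw their means from an equal
mixture of Beta(2,10) and Beta(10,2), reproducing the bimodal beta
landscape of real arrays. Per-entry noise is normal on the logit scale
(sd 0.05) and values are mapped back through the logistic, so betas stay in
(0,1) and the bimodality is preserved. Probe artifacts are planted as
mutually disjoint sets — 1000 sex-chromosome, 500 SNP-overlap, 500
multi-mapping, 200 detection-failure probes — never intersecting the
informative probes, so the filter tally is exactly predictable
(20000 − 2200 = 17800 retained).

What the generator does not emulate: batch/array effects, probe-type
chemistry differences, correlated probe blocks within CpG islands, tumor
purity gradients, or missing values. Group recovery on this generator
verifies the clustering machinery, not robustness to those artifacts.

# Numerical choices and degenerate inputs

* Pseudocount 1 on both sides of the log2 ratio; configurable.
* Group means in the Wald test add 0.5 total per group to stay defined at
  zero counts; the dispersion trend is floored at 1e-8.
* Hypergeometric downsampling runs in canonical (sorted construct) order
  with one random substream per sample, so results are invariant to row and
  column order of the input.
* All randomness flows from one root seed through named substreams
  (simulation, downsampling, consensus), so stages are independently
  reproducible and byte-identical under a repeated seed.
* k-means++ centers that collide (possible only with duplicated samples)
  fall back to distinct random rows; an empty or failed k-means restart is
  skipped and the best of the remaining restarts kept.
* Degenerate inputs error early with the offending name: zero-total
  samples, constant samples (undefined rank correlation), fewer than 10
  surviving NTCs, fewer samples than max(k)+1, sample pairs never
  co-sampled (too few resamples), k outside the evaluated range.

# Problem sizes

The shipped defaults are desk-scale by intent: 2000 genes + 100 NTC pairs
at depth 500 for the screen (seconds to simulate and score), and a
119-sample, 20,000-probe cohort for the methylation pipeline (a full
1000-resample consensus run over k = 2..8 takes on the order of 90
seconds). The full-scale screen composition (23,483 genes, 1137 NTC pairs)
is available as a preset; nothing in the code depends on the desk-scale
sizes.

# Known limitations

* The Wald test's dispersion model (method of moments with 50/50 trend
  shrinkage) is simpler than the empirical-Bayes machinery of dedicated
  count-model packages; with three replicates per arm its p-values are
  calibrated but not identical to any such package.
* Gene-level and construct-level results coincide for one-construct-per-
  gene libraries; libraries with several constructs per gene are aggregated
  by the construct of maximal |z| (with a note), which ignores
  within-gene concordance.
* The consensus k-selection reports, but does not automate judgment on,
  cohorts whose true structure is hierarchical (groups with genuine
  subgroups); the silhouette criterion will prefer the coarser level when
  separations are comparable.
* Spearman distance discards all magnitude information; two samples that
  differ by a global methylation shift but preserve probe ordering are
  treated as identical.
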
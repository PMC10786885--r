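# screenmeth

Tools for two analyses used in functional-genomic studies of Schwann cell
tumors (neurofibromas, schwannomas, MPNSTs) and comparable systems:

1. **Dual-condition CRISPRi screen scoring.** A pooled dual-sgRNA screen is
   grown under vehicle and drug (e.g. the MEK inhibitor selumetinib) arms
   against a shared post-transduction baseline (T0). From construct counts,
   the pipeline computes per-replicate log2 ratios
   `L = log2((c_T10 + 1)/(c_T0 + 1))` on depth-equalized counts, converts
   them to phenotype scores per population doubling centered on the
   non-targeting controls,
   `phen = (mean L − median_NTC L) / D`, `z = phen / sd_NTC(phen)`,
   tests each construct with a per-construct negative-binomial Wald test
   (Benjamini–Hochberg adjusted), and classifies hits as shared or
   condition-selective enriched/depleted. This is how a drug-resistance
   driver such as *NF2* surfaces as a shared-enriched hit while Ras-pathway
   activators surface as drug-selective depleted hits.
2. **DNA methylation grouping.** From a probes × samples beta-value matrix,
   the pipeline filters probes (sex chromosomes, SNP overlap, multi-mapping,
   detection p ≥ 0.05 in any sample), selects the most variable probes, and
   groups samples by consensus k-means over 1000 sample resamples in
   Spearman-correlation geometry, `d(i,j) = 1 − ρ_Spearman`. The number of
   groups is chosen by the silhouette maximum of the consensus partition on
   the Spearman distance, with the consensus-CDF area curve (A(k), Δ(k)) as
   the corroborating stability diagnostic, and cross-checked by Ward
   hierarchical clustering.

A seeded synthetic-data module (`simulateScreen()`, `simulateMethylation()`)
generates both input types with planted ground truth — essential /
fitness-suppressor / resistance / sensitizer genes for the screen; planted
sample groups and flagged probes for methylation — so every stage is
verified end to end at desk scale.

The package is written Bioconductor-style: screen counts live in a
`ScreenExperiment` and beta values in a `MethylationExperiment` (both
`SummarizedExperiment` subclasses), consensus output in a
`ConsensusResult` with accessors (`selectedK()`, `consensusMatrix()`,
`groupLabels()`, `kDiagnostics()`).

## Worked example: screen scoring

```r
library(screenmeth)
sim <- simulateScreen(ScreenSimConfig(seed = 7))   # 2000 genes + 100 NTCs
res <- scoreScreen(sim$experiment)                  # doublings: vehicle 8, drug 6
table(res$hit_class)
#>         shared_enriched         shared_depleted drug_selective_enriched
#>                      42                     197                      22
#> drug_selective_depleted   vehicle_only_enriched   vehicle_only_depleted
#>                      29                      23                       1
#>         not_significant
#>                    1783
```

2097 of 2100 constructs pass the 50-read filter. All 20 planted resistance
genes are recovered among the 22 `drug_selective_enriched` hits (enriched
under drug only: suppressing these genes confers drug resistance) and all 20
sensitizers among the 29 `drug_selective_depleted`; the 197 planted
essential genes that survive filtering are all `shared_depleted`. Essential
QC: 197/197 significantly depleted, 0 enriched — a passing screen.

```r
S4Vectors::metadata(res)$ntc_stats
#>       arm median_log2_ratio sd_phenotype n_ntc
#>   vehicle      0.0590333504   0.01257365   100
#>      drug      0.0002119817   0.01829676   100
```

The NTC spread (`sd_phenotype`, per doubling) is the unit of the z score.

## Worked example: methylation grouping

```r
sim <- simulateMethylation(MethSimConfig(seed = 1))  # 119 samples, groups 25/8/86
se  <- filterProbes(sim$experiment)                  # 17800 of 20000 probes kept
sel <- selectVariableProbes(se, 10000)
res <- evaluateK(consensusCluster(sel, k_range = 2:8,
                                  n_resamples = 1000, seed = 1))
kDiagnostics(res)
#>   k       auc  delta_auc mean_silhouette
#> 1 2 0.4057054 0.40570538           0.869
#> 2 3 0.4341201 0.07003791           0.970
#> 3 4 0.6929494 0.59621566           0.272
#> 4 5 0.7796532 0.12512288           0.271
#> 5 6 0.8212851 0.05339796           0.271
#> 6 7 0.8479280 0.03244054           0.271
#> 7 8 0.8687356 0.02453932           0.271
selectedK(res)
#> [1] 3
```

The silhouette peaks sharply at k = 3 (0.97) and collapses beyond it —
splitting a real group no longer separates samples that are far apart in
the data — so three groups are selected, recovering the planted 25/8/86
partition (adjusted Rand index ≥ 0.9; identical at 1000, 10,000 or 15,000
variable probes). The full run takes about 90 seconds.

File-based orchestration (TSV in, `results.tsv` / `labels.tsv` /
`summary.json` + resolved config out) is available through `runScreen()`
and `runMethylationGrouping()`; see the vignette in `vignettes/` for the
models, parameter meanings and design rationale.

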
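Package: screenmeth
Title: CRISPRi Screen Phenotype Scoring and DNA Methylation Consensus Grouping
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two analyses used in functional-genomic studies of
    Schwann cell tumors and similar systems. The screen pipeline scores pooled
    dual-sgRNA CRISPRi screens run under two conditions (vehicle and drug)
    against a shared baseline: read depth equalization by hypergeometric
    downsampling, low-abundance filtering, per-replicate log2 ratios,
    population-doubling and non-targeting-control normalized phenotype scores,
    per-construct negative-binomial Wald tests with Benjamini-Hochberg
    adjustment, hit classification into shared and condition-selective
    enriched/depleted sets, and essential-gene depletion quality control. The
    methylation pipeline groups samples from beta-value matrices: probe
    filtering (sex chromosomes, SNP overlap, multi-mapping, detection p-value),
    variable-probe selection, Spearman-correlation distance, consensus k-means
    clustering over sample resamples, CDF/delta-AUC plus silhouette selection
    of the number of groups, and a Ward hierarchical cross-check. Seeded
    synthetic-data generators with planted ground truth emulate both input
    types so every stage can be verified at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    data.table,
    jsonlite,
    yaml,
    cluster,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: CRISPR, FunctionalGenomics, DNAMethylation, Clustering, Software
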
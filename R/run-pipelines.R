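# End-to-end orchestrators: file inputs -> scored outputs + machine-readable
# summaries. Errors are signalled as R conditions with single-line messages;
# on success the functions return invisibly with status 0.

.resolveConfig <- function(config, defaults, what) {
    if (is.character(config) && length(config) == 1L) {
        if (!file.exists(config)) stop(what, " config file not found: ",
                                       config)
        config <- yaml::read_yaml(config)
    }
    if (!is.list(config)) stop(what, " config must be a list or a YAML path")
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown ", what, " config key(s): ",
             paste(unknown, collapse = ", "))
    utils::modifyList(defaults, config)
}

.writeRunRecord <- function(out, cfg, summary) {
    dir.create(out, showWarnings = FALSE, recursive = TRUE)
    cfg$package_version <- as.character(utils::packageVersion("screenmeth"))
    writeLines(yaml::as.yaml(cfg), file.path(out, "config.yaml"))
    jsonlite::write_json(summary, file.path(out, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the screen scoring pipeline on input files
#'
#' Reads the counts/library/sample-sheet files, scores the screen
#' (\code{\link{scoreScreen}}: downsample, filter, log2 ratios, phenotypes,
#' Wald tests, hit classification), optionally runs essential-gene QC, and
#' writes \code{results.tsv}, \code{summary.json} and the resolved
#' \code{config.yaml} into the output directory.
#'
#' @param config a named list or path to a YAML file with keys:
#'   \code{counts}, \code{library}, \code{samples} (input paths), \code{out}
#'   (output directory), \code{doublings_vehicle}, \code{doublings_drug},
#'   \code{alpha}, \code{min_mean}, \code{pseudocount}, \code{seed},
#'   \code{essential_genes} (optional path to a one-column text file of gene
#'   symbols). Unknown keys are rejected.
#' @return Invisibly, a list with \code{status} (0), \code{results} (the
#'   \linkS4class{ScreenResults}) and \code{summary}.
#' @export
runScreen <- function(config) {
    defaults <- list(counts = NULL, library = NULL, samples = NULL,
                     out = NULL, doublings_vehicle = 8, doublings_drug = 6,
                     alpha = 0.05, min_mean = 50, pseudocount = 1,
                     seed = 1L, essential_genes = NULL)
    cfg <- .resolveConfig(config, defaults, "screen")
    for (key in c("counts", "library", "samples", "out"))
        if (is.null(cfg[[key]])) stop("screen config key '", key,
                                      "' is required")
    cts <- readScreenCounts(cfg$counts)
    lib <- readScreenLibrary(cfg$library)
    sheet <- readSampleSheet(cfg$samples)
    for (arm in c("vehicle", "drug"))
        if (!arm %in% sheet$arm)
            stop("sample sheet has no '", arm, "' arm")
    se <- ScreenExperiment(cts, lib, sheet)
    doublings <- c(vehicle = cfg$doublings_vehicle,
                   drug = cfg$doublings_drug)
    res <- scoreScreen(se, doublings = doublings, alpha = cfg$alpha,
                       min_mean = cfg$min_mean,
                       pseudocount = cfg$pseudocount, seed = cfg$seed)
    message("NTC normalization: ",
            paste(sprintf("%s median=%.4g sd=%.4g n=%d",
                          metadata(res)$ntc_stats$arm,
                          metadata(res)$ntc_stats$median_log2_ratio,
                          metadata(res)$ntc_stats$sd_phenotype,
                          metadata(res)$ntc_stats$n_ntc), collapse = "; "))
    summary <- list(
        n_constructs_input = nrow(cts),
        n_constructs_tested = nrow(res),
        n_excluded = length(metadata(res)$excluded_constructs),
        ntc_stats = metadata(res)$ntc_stats,
        hit_class_counts = as.list(table(res$hit_class)),
        doublings = as.list(doublings),
        alpha = cfg$alpha, min_mean = cfg$min_mean, seed = cfg$seed)
    if (!is.null(cfg$essential_genes)) {
        ess <- readLines(cfg$essential_genes)
        qc <- qcEssentialDepletion(
            data.frame(gene = res$gene, mean_log2fc = res$vehicle_log2fc,
                       padj = res$vehicle_padj),
            ess, alpha = cfg$alpha)
        summary$essential_qc <- qc
    }
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    writeScreenResults(res, file.path(cfg$out, "results.tsv"))
    .writeRunRecord(cfg$out, cfg, summary)
    invisible(list(status = 0L, results = res, summary = summary))
}

#' Run the methylation grouping pipeline on input files
#'
#' Reads beta/detection-p/probe-annotation files, filters probes, selects
#' the most variable probes, runs Spearman-distance consensus k-means,
#' selects k by CDF delta-AUC plus silhouette, assigns groups, cross-checks
#' with Ward hierarchical clustering, and writes \code{labels.tsv},
#' per-k \code{consensus_k<K>.tsv} matrices, \code{summary.json} and the
#' resolved \code{config.yaml}.
#'
#' @param config a named list or YAML path with keys: \code{beta},
#'   \code{detp}, \code{probes} (input paths), \code{out} (output
#'   directory), \code{k_min}, \code{k_max}, \code{n_probes},
#'   \code{resamples}, \code{fraction}, \code{auc_gain_threshold},
#'   \code{hierarchical_probes}, \code{seed}. Unknown keys are rejected.
#' @return Invisibly, a list with \code{status} (0), \code{result} (the
#'   evaluated \linkS4class{ConsensusResult}), \code{labels} and
#'   \code{summary}.
#' @export
runMethylationGrouping <- function(config) {
    defaults <- list(beta = NULL, detp = NULL, probes = NULL, out = NULL,
                     k_min = 2L, k_max = 8L, n_probes = 10000L,
                     resamples = 1000L, fraction = 0.8,
                     auc_gain_threshold = 0.10,
                     hierarchical_probes = 5000L, seed = 1L)
    cfg <- .resolveConfig(config, defaults, "methylation")
    for (key in c("beta", "detp", "probes", "out"))
        if (is.null(cfg[[key]])) stop("methylation config key '", key,
                                      "' is required")
    beta <- readBetaMatrix(cfg$beta)
    if (anyNA(beta) || min(beta) < 0 || max(beta) > 1) {
        bad <- which(is.na(beta) | beta < 0 | beta > 1, arr.ind = TRUE)[1, ]
        stop(sprintf("invalid beta value at probe %s, sample %s",
                     rownames(beta)[bad[1]], colnames(beta)[bad[2]]))
    }
    detp <- readDetectionP(cfg$detp)
    ann <- readProbeAnnotation(cfg$probes)
    if (cfg$k_max > ncol(beta) - 1L)
        stop("k_max (", cfg$k_max, ") must be at most n_samples - 1 = ",
             ncol(beta) - 1L,
             " so every evaluated k leaves more samples than clusters")
    se <- MethylationExperiment(beta, ann, detp = detp)
    se <- filterProbes(se)
    tally <- metadata(se)$filter_tally
    message("probe filter: ", tally$retained, " of ", tally$input,
            " probes retained")
    sel <- selectVariableProbes(se, cfg$n_probes)
    res <- consensusCluster(sel, k_range = seq.int(cfg$k_min, cfg$k_max),
                            n_resamples = cfg$resamples,
                            item_fraction = cfg$fraction, seed = cfg$seed)
    res <- evaluateK(res, auc_gain_threshold = cfg$auc_gain_threshold)
    labels <- assignGroups(res)
    hier <- hierarchicalCheck(se, k = selectedK(res),
                              n_probes = cfg$hierarchical_probes,
                              reference_labels = stats::setNames(
                                  labels$group, labels$sample_id))
    message("selected k = ", selectedK(res),
            "; hierarchical cross-check ARI = ", round(hier$ari, 3))
    dir.create(cfg$out, showWarnings = FALSE, recursive = TRUE)
    data.table::fwrite(labels, file.path(cfg$out, "labels.tsv"), sep = "\t")
    for (k in consensusK(res)) {
        M <- consensusMatrix(res, k)
        data.table::fwrite(data.frame(sample_id = rownames(M), M,
                                      check.names = FALSE),
                           file.path(cfg$out,
                                     sprintf("consensus_k%d.tsv", k)),
                           sep = "\t")
    }
    diag <- kDiagnostics(res)
    summary <- list(k_range = consensusK(res),
                    auc = diag$auc, delta_auc = diag$delta_auc,
                    mean_silhouette = diag$mean_silhouette,
                    selected_k = selectedK(res),
                    probe_filter = tally,
                    n_variable_probes = min(cfg$n_probes, tally$retained),
                    hierarchical_ari = hier$ari,
                    resamples = cfg$resamples, fraction = cfg$fraction,
                    seed = cfg$seed)
    .writeRunRecord(cfg$out, cfg, summary)
    invisible(list(status = 0L, result = res, labels = labels,
                   summary = summary))
}
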
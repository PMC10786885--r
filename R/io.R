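# Readers and writers for the plain-text interchange formats.

#' Read screen input files
#'
#' \code{readScreenLibrary} reads a tab-separated library registry
#' (\code{construct_id, gene, protospacer_a, protospacer_b, is_ntc});
#' \code{readScreenCounts} reads a counts TSV (\code{construct_id} then one
#' integer column per sample); \code{readSampleSheet} reads a CSV sample
#' sheet (\code{sample_id, arm, timepoint, replicate}).
#'
#' @param path file path.
#' @return A data.frame (\code{readScreenLibrary},
#'   \code{readSampleSheet}) or integer matrix with construct rownames
#'   (\code{readScreenCounts}).
#' @name screen-io
NULL

.readTable <- function(path, sep, required, what) {
    if (!file.exists(path)) stop(what, " file not found: ", path)
    d <- as.data.frame(data.table::fread(path, sep = sep, header = TRUE))
    missing <- setdiff(required, colnames(d))
    if (length(missing))
        stop(what, " file ", path, " is missing column(s): ",
             paste(missing, collapse = ", "))
    d
}

#' @rdname screen-io
#' @export
readScreenLibrary <- function(path) {
    d <- .readTable(path, "\t", c("construct_id", "gene", "protospacer_a",
                                  "protospacer_b", "is_ntc"), "library")
    d$is_ntc <- as.logical(as.integer(d$is_ntc))
    d
}

#' @rdname screen-io
#' @export
readScreenCounts <- function(path) {
    d <- .readTable(path, "\t", "construct_id", "counts")
    m <- as.matrix(d[, setdiff(colnames(d), "construct_id"), drop = FALSE])
    rownames(m) <- d$construct_id
    storage.mode(m) <- "integer"
    m
}

#' @rdname screen-io
#' @export
readSampleSheet <- function(path) {
    .readTable(path, ",", c("sample_id", "arm", "timepoint", "replicate"),
               "sample sheet")
}

#' Read methylation input files
#'
#' \code{readBetaMatrix} and \code{readDetectionP} read probes x samples TSV
#' matrices (\code{probe_id} then one float column per sample);
#' \code{readProbeAnnotation} reads a probe annotation TSV
#' (\code{probe_id, chrom, snp_overlap, multimap}).
#'
#' @param path file path.
#' @return A numeric matrix with probe rownames, or a data.frame for the
#'   annotation.
#' @name meth-io
NULL

.readMatrixTsv <- function(path, what) {
    d <- .readTable(path, "\t", "probe_id", what)
    m <- as.matrix(d[, setdiff(colnames(d), "probe_id"), drop = FALSE])
    rownames(m) <- d$probe_id
    m
}

#' @rdname meth-io
#' @export
readBetaMatrix <- function(path) .readMatrixTsv(path, "beta")

#' @rdname meth-io
#' @export
readDetectionP <- function(path) .readMatrixTsv(path, "detection p")

#' @rdname meth-io
#' @export
readProbeAnnotation <- function(path) {
    d <- .readTable(path, "\t", c("probe_id", "chrom", "snp_overlap",
                                  "multimap"), "probe annotation")
    d$snp_overlap <- as.logical(as.integer(d$snp_overlap))
    d$multimap <- as.logical(as.integer(d$multimap))
    d
}

#' Write simulated inputs in the pipelines' file formats
#'
#' Writes the files the orchestrators read -- screen: \code{library.tsv},
#' \code{counts.tsv}, \code{samples.csv}; methylation: \code{beta.tsv},
#' \code{detp.tsv}, \code{probes.tsv} -- plus \code{truth.tsv} with the
#' planted labels and the generator configuration echoed as
#' \code{sim_config.yaml}.
#'
#' @param sim output of \code{\link{simulateScreen}} or
#'   \code{\link{simulateMethylation}}.
#' @param dir output directory (created if absent).
#' @return Invisibly, the vector of written file paths.
#' @name write-inputs
NULL

.configAsList <- function(config) {
    out <- lapply(slotNames(config), function(s) {
        v <- slot(config, s)
        if (!is.null(names(v))) as.list(v) else v
    })
    names(out) <- slotNames(config)
    out
}

#' @rdname write-inputs
#' @export
writeScreenInputs <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    se <- sim$experiment
    paths <- file.path(dir, c("library.tsv", "counts.tsv", "samples.csv",
                              "truth.tsv", "sim_config.yaml"))
    lib <- data.frame(construct_id = rownames(se),
                      gene = rowData(se)$gene,
                      protospacer_a = rowData(se)$protospacer_a,
                      protospacer_b = rowData(se)$protospacer_b,
                      is_ntc = as.integer(rowData(se)$is_ntc))
    data.table::fwrite(lib, paths[1], sep = "\t")
    cts <- data.frame(construct_id = rownames(se),
                      assay(se, "counts"), check.names = FALSE)
    data.table::fwrite(cts, paths[2], sep = "\t")
    sheet <- data.frame(sample_id = colnames(se),
                        arm = colData(se)$arm,
                        timepoint = colData(se)$timepoint,
                        replicate = colData(se)$replicate)
    data.table::fwrite(sheet, paths[3], sep = ",")
    data.table::fwrite(sim$truth, paths[4], sep = "\t")
    writeLines(yaml::as.yaml(.configAsList(metadata(se)$sim_config)),
               paths[5])
    invisible(paths)
}

#' @rdname write-inputs
#' @export
writeMethylationInputs <- function(sim, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    se <- sim$experiment
    paths <- file.path(dir, c("beta.tsv", "detp.tsv", "probes.tsv",
                              "truth.tsv", "sim_config.yaml"))
    beta <- data.frame(probe_id = rownames(se), assay(se, "beta"),
                       check.names = FALSE)
    data.table::fwrite(beta, paths[1], sep = "\t")
    detp <- data.frame(probe_id = rownames(se), assay(se, "detp"),
                       check.names = FALSE)
    data.table::fwrite(detp, paths[2], sep = "\t")
    ann <- data.frame(probe_id = rownames(se),
                      chrom = rowData(se)$chrom,
                      snp_overlap = as.integer(rowData(se)$snp_overlap),
                      multimap = as.integer(rowData(se)$multimap))
    data.table::fwrite(ann, paths[3], sep = "\t")
    data.table::fwrite(sim$truth$samples, paths[4], sep = "\t")
    writeLines(yaml::as.yaml(.configAsList(metadata(se)$sim_config)),
               paths[5])
    invisible(paths)
}

#' Write a screen results table as TSV
#'
#' @param results a \linkS4class{ScreenResults} object.
#' @param path output file.
#' @return Invisibly, \code{path}.
#' @export
writeScreenResults <- function(results, path) {
    d <- as.data.frame(results)
    d <- cbind(construct_id = rownames(d), d)
    data.table::fwrite(d, path, sep = "\t")
    invisible(path)
}
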
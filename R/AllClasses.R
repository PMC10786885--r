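#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<- SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay assay<- assays
#'   assayNames rowData colData
NULL

.SCREEN_ARMS <- c("baseline", "vehicle", "drug")
.SCREEN_TIMEPOINTS <- c("T0", "T10")

#' Container for pooled CRISPRi screen counts
#'
#' A \linkS4class{SummarizedExperiment} holding one integer assay
#' \code{"counts"} (constructs x samples). \code{rowData} carries the library
#' registry (\code{gene}, \code{protospacer_a}, \code{protospacer_b},
#' \code{is_ntc}); \code{colData} carries the sample sheet (\code{arm},
#' \code{timepoint}, \code{replicate}). Validity enforces unique construct
#' identifiers, non-negative counts, \code{is_ntc} if and only if the gene is
#' \code{"NTC"}, and \code{arm == "baseline"} if and only if
#' \code{timepoint == "T0"}.
#'
#' @aliases ScreenExperiment-class
#' @exportClass ScreenExperiment
setClass("ScreenExperiment", contains = "SummarizedExperiment")

setValidity("ScreenExperiment", function(object) {
    msg <- character()
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(cts < 0)) msg <- c(msg, "counts must be non-negative")
        if (any(abs(cts - round(cts)) > 1e-8))
            msg <- c(msg, "counts must be integers")
    }
    rd <- rowData(object)
    need_rd <- c("gene", "protospacer_a", "protospacer_b", "is_ntc")
    if (!all(need_rd %in% colnames(rd)))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(need_rd, collapse = ", ")))
    else {
        if (anyDuplicated(rownames(object)))
            msg <- c(msg, "construct ids (rownames) must be unique")
        bad <- xor(rd$is_ntc, rd$gene == "NTC")
        if (any(bad))
            msg <- c(msg, paste0("is_ntc must match gene == 'NTC' (offending: ",
                                 paste(head(rownames(object)[bad], 3),
                                       collapse = ", "), ")"))
    }
    cd <- colData(object)
    need_cd <- c("arm", "timepoint", "replicate")
    if (!all(need_cd %in% colnames(cd)))
        msg <- c(msg, paste0("colData must contain: ",
                             paste(need_cd, collapse = ", ")))
    else {
        if (!all(cd$arm %in% .SCREEN_ARMS))
            msg <- c(msg, "arm must be one of baseline/vehicle/drug")
        if (!all(cd$timepoint %in% .SCREEN_TIMEPOINTS))
            msg <- c(msg, "timepoint must be T0 or T10")
        bad <- xor(cd$arm == "baseline", cd$timepoint == "T0")
        if (any(bad))
            msg <- c(msg, "arm 'baseline' must coincide with timepoint 'T0'")
        key <- paste(cd$arm, cd$timepoint, cd$replicate)
        if (anyDuplicated(key))
            msg <- c(msg, "arm/timepoint/replicate triples must be unique")
    }
    if (length(msg)) msg else TRUE
})

#' Construct a ScreenExperiment
#'
#' @param counts integer matrix, constructs x samples; rownames are construct
#'   ids, colnames are sample ids.
#' @param library data.frame with columns \code{construct_id}, \code{gene},
#'   \code{protospacer_a}, \code{protospacer_b}, \code{is_ntc}.
#' @param samples data.frame with columns \code{sample_id}, \code{arm}
#'   (\code{baseline}/\code{vehicle}/\code{drug}), \code{timepoint}
#'   (\code{T0}/\code{T10}), \code{replicate}.
#' @return A \linkS4class{ScreenExperiment}.
#' @examples
#' lib <- data.frame(construct_id = c("c1", "n1"), gene = c("GENE1", "NTC"),
#'                   protospacer_a = c("ACGT", "TTTT"),
#'                   protospacer_b = c("GGGG", "CCCC"),
#'                   is_ntc = c(FALSE, TRUE))
#' sam <- data.frame(sample_id = c("T0", "V1"),
#'                   arm = c("baseline", "vehicle"),
#'                   timepoint = c("T0", "T10"), replicate = c(1L, 1L))
#' cts <- matrix(1:4, 2, dimnames = list(lib$construct_id, sam$sample_id))
#' ScreenExperiment(cts, lib, sam)
#' @export
ScreenExperiment <- function(counts, library, samples) {
    library <- as.data.frame(library)
    samples <- as.data.frame(samples)
    if (is.null(rownames(counts)))
        stop("counts must have construct ids as rownames")
    if (is.null(colnames(counts)))
        stop("counts must have sample ids as colnames")
    if (!all(rownames(counts) %in% library$construct_id)) {
        missing <- setdiff(rownames(counts), library$construct_id)
        stop("counts rows absent from library: ",
             paste(head(missing, 5), collapse = ", "))
    }
    library <- library[match(rownames(counts), library$construct_id), ]
    if (!all(colnames(counts) %in% samples$sample_id)) {
        missing <- setdiff(colnames(counts), samples$sample_id)
        stop("counts columns absent from sample sheet: ",
             paste(head(missing, 5), collapse = ", "))
    }
    samples <- samples[match(colnames(counts), samples$sample_id), ]
    rd <- DataFrame(gene = library$gene,
                    protospacer_a = library$protospacer_a,
                    protospacer_b = library$protospacer_b,
                    is_ntc = as.logical(library$is_ntc),
                    row.names = library$construct_id)
    cd <- DataFrame(arm = as.character(samples$arm),
                    timepoint = as.character(samples$timepoint),
                    replicate = as.integer(samples$replicate),
                    row.names = samples$sample_id)
    storage.mode(counts) <- "integer"
    se <- SummarizedExperiment(assays = list(counts = counts),
                               rowData = rd, colData = cd)
    new("ScreenExperiment", se)
}

#' Container for methylation beta values
#'
#' A \linkS4class{SummarizedExperiment} with assay \code{"beta"} (probes x
#' samples, values in [0, 1]) and optionally \code{"detp"} (detection
#' p-values, same shape). \code{rowData} carries the probe annotation used by
#' \code{\link{filterProbes}}: \code{chrom}, \code{snp_overlap},
#' \code{multimap}.
#'
#' @aliases MethylationExperiment-class
#' @exportClass MethylationExperiment
setClass("MethylationExperiment", contains = "SummarizedExperiment")

setValidity("MethylationExperiment", function(object) {
    msg <- character()
    if (!"beta" %in% assayNames(object))
        msg <- c(msg, "assay 'beta' is required")
    else {
        b <- assay(object, "beta")
        if (anyNA(b)) msg <- c(msg, "beta values must not be missing")
        else if (min(b) < 0 || max(b) > 1) {
            bad <- which(b < 0 | b > 1, arr.ind = TRUE)[1, ]
            msg <- c(msg, sprintf(
                "beta values must lie in [0, 1] (probe %s, sample %s: %g)",
                rownames(object)[bad[1]], colnames(object)[bad[2]],
                b[bad[1], bad[2]]))
        }
    }
    if ("detp" %in% assayNames(object)) {
        dp <- assay(object, "detp")
        if (anyNA(dp) || min(dp) < 0 || max(dp) > 1)
            msg <- c(msg, "detection p-values must lie in [0, 1]")
    }
    rd <- rowData(object)
    need <- c("chrom", "snp_overlap", "multimap")
    if (!all(need %in% colnames(rd)))
        msg <- c(msg, paste0("rowData must contain: ",
                             paste(need, collapse = ", ")))
    if (anyDuplicated(rownames(object)))
        msg <- c(msg, "probe ids (rownames) must be unique")
    if (length(msg)) msg else TRUE
})

#' Construct a MethylationExperiment
#'
#' @param beta numeric matrix in [0, 1], probes x samples, with dimnames.
#' @param annotation data.frame with columns \code{probe_id}, \code{chrom},
#'   \code{snp_overlap}, \code{multimap}.
#' @param detp optional numeric matrix of detection p-values, same shape as
#'   \code{beta}.
#' @return A \linkS4class{MethylationExperiment}.
#' @export
MethylationExperiment <- function(beta, annotation, detp = NULL) {
    annotation <- as.data.frame(annotation)
    if (is.null(rownames(beta)) || is.null(colnames(beta)))
        stop("beta must have probe ids as rownames and sample ids as colnames")
    if (!all(rownames(beta) %in% annotation$probe_id)) {
        missing <- setdiff(rownames(beta), annotation$probe_id)
        stop("probes absent from annotation: ",
             paste(head(missing, 5), collapse = ", "))
    }
    annotation <- annotation[match(rownames(beta), annotation$probe_id), ]
    rd <- DataFrame(chrom = as.character(annotation$chrom),
                    snp_overlap = as.logical(annotation$snp_overlap),
                    multimap = as.logical(annotation$multimap),
                    row.names = annotation$probe_id)
    assays <- list(beta = beta)
    if (!is.null(detp)) {
        if (!identical(dim(detp), dim(beta)))
            stop("detp must have the same shape as beta")
        dimnames(detp) <- dimnames(beta)
        assays$detp <- detp
    }
    se <- SummarizedExperiment(assays = assays, rowData = rd)
    new("MethylationExperiment", se)
}

#' Consensus clustering result
#'
#' Holds, for each evaluated number of groups k: the sample x sample consensus
#' matrix (fraction of resamples in which two co-sampled items co-clustered),
#' group labels from average-linkage clustering of 1 - M(k), and, after
#' \code{\link{evaluateK}}, the consensus CDF, its area A(k), the relative
#' area increment delta(k), mean silhouette widths, and the selected k.
#'
#' @slot sampleIds character, sample identifiers.
#' @slot ks integer vector of evaluated k.
#' @slot consensus named list of consensus matrices, one per k.
#' @slot labels integer matrix, samples x length(ks), group labels per k.
#' @slot cdfGrid numeric grid on [0, 1] where the consensus CDF is evaluated.
#' @slot cdf named list of CDF values per k (filled by \code{evaluateK}).
#' @slot auc numeric A(k) per k.
#' @slot deltaAuc numeric delta(k) per k.
#' @slot silhouette numeric mean silhouette width per k.
#' @slot selectedK integer, the selected number of groups (NA until evaluated).
#' @slot dataDist sample x sample Spearman correlation distance of the
#'   clustered data, used for silhouette widths.
#' @slot params list of run parameters (resamples, fraction, seed, ...).
#' @slot assignments list of per-resample draws (only when requested).
#' @aliases ConsensusResult-class
#' @exportClass ConsensusResult
setClass("ConsensusResult",
    representation(sampleIds = "character", ks = "integer",
                   consensus = "list", labels = "matrix",
                   cdfGrid = "numeric", cdf = "list", auc = "numeric",
                   deltaAuc = "numeric", silhouette = "numeric",
                   selectedK = "integer", dataDist = "matrix",
                   params = "list", assignments = "list"))

setValidity("ConsensusResult", function(object) {
    msg <- character()
    if (length(object@consensus) != length(object@ks))
        msg <- c(msg, "one consensus matrix per k is required")
    n <- length(object@sampleIds)
    for (i in seq_along(object@consensus)) {
        M <- object@consensus[[i]]
        if (!all(dim(M) == n)) {
            msg <- c(msg, "consensus matrices must be sample x sample")
            break
        }
        if (max(abs(M - t(M))) > 1e-12)
            msg <- c(msg, sprintf("consensus matrix k=%d is not symmetric",
                                  object@ks[i]))
        if (any(abs(diag(M) - 1) > 1e-12))
            msg <- c(msg, sprintf("consensus matrix k=%d diagonal is not 1",
                                  object@ks[i]))
        if (min(M) < -1e-12 || max(M) > 1 + 1e-12)
            msg <- c(msg, sprintf("consensus entries k=%d outside [0, 1]",
                                  object@ks[i]))
    }
    if (length(msg)) msg else TRUE
})

setMethod("show", "ConsensusResult", function(object) {
    cat("ConsensusResult:", length(object@sampleIds), "samples, k =",
        paste(range(object@ks), collapse = ".."), "\n")
    if (!is.na(object@selectedK)) {
        cat("selected k:", object@selectedK, "\n")
        d <- kDiagnostics(object)
        print(d, row.names = FALSE)
    } else {
        cat("diagnostics not yet computed; run evaluateK()\n")
    }
    invisible(object)
})
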
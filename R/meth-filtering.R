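#' Filter methylation probes by annotation and detection quality
#'
#' Retains probes that (i) do not map to the X or Y chromosome, (ii) do not
#' overlap a common SNP, (iii) map uniquely, and (iv) have detection
#' p-value below \code{p_thresh} in every sample. The removal tally
#' attributes each removed probe to the first matching rule in that order
#' (all rules are applied).
#'
#' @param x a \linkS4class{MethylationExperiment} with assays \code{beta} and
#'   \code{detp}.
#' @param p_thresh detection p-value threshold; a probe is removed if its
#'   detection p is \code{>= p_thresh} in any sample.
#' @return The filtered \linkS4class{MethylationExperiment};
#'   \code{metadata(x)$filter_tally} records removals per rule and the
#'   retained probe count.
#' @export
filterProbes <- function(x, p_thresh = 0.05) {
    stopifnot(is(x, "MethylationExperiment"))
    if (!"detp" %in% assayNames(x))
        stop("assay 'detp' (detection p-values) is required")
    rd <- rowData(x)
    sex <- rd$chrom %in% c("chrX", "chrY", "X", "Y")
    snp <- rd$snp_overlap
    mm <- rd$multimap
    det <- apply(assay(x, "detp") >= p_thresh, 1L, any)
    rule <- rep(NA_character_, nrow(x))
    rule[det] <- "detection_fail"
    rule[mm] <- "multimap"
    rule[snp] <- "snp_overlap"
    rule[sex] <- "sex_chrom"   # first-matching rule wins, applied last
    keep <- is.na(rule)
    tally <- c(sex_chrom = sum(rule == "sex_chrom", na.rm = TRUE),
               snp_overlap = sum(rule == "snp_overlap", na.rm = TRUE),
               multimap = sum(rule == "multimap", na.rm = TRUE),
               detection_fail = sum(rule == "detection_fail", na.rm = TRUE))
    out <- x[keep, ]
    metadata(out)$filter_tally <- c(as.list(tally),
                                    list(retained = sum(keep),
                                         input = nrow(x),
                                         p_thresh = p_thresh))
    out
}

#' Select the most variable probes
#'
#' Ranks probes by the standard deviation of beta across samples (descending;
#' ties broken by probe id in lexicographic order) and keeps the top
#' \code{n}. Asking for more probes than available returns everything with a
#' warning.
#'
#' @param x a \linkS4class{MethylationExperiment} or a beta matrix.
#' @param n number of probes to keep (at least 2).
#' @return Object of the same class as \code{x}, restricted to the selected
#'   probes, in ranked order.
#' @export
selectVariableProbes <- function(x, n) {
    if (n < 2) stop("n must be at least 2")
    b <- if (is(x, "SummarizedExperiment")) assay(x, "beta") else x
    if (n >= nrow(b)) {
        if (n > nrow(b))
            warning("requested ", n, " probes but only ", nrow(b),
                    " available; keeping all")
        return(x)
    }
    sds <- .rowSds(b)
    ord <- order(-sds, rownames(b))
    x[ord[seq_len(n)], ]
}

#' Spearman-correlation distance between samples
#'
#' \code{d(i, j) = 1 - rho_Spearman(sample_i, sample_j)} across probes, with
#' average ranks for ties. The rank correlation is preferred for beta values
#' because of their non-normal, bimodal distribution.
#'
#' @param x a \linkS4class{MethylationExperiment} or a probes x samples
#'   matrix with at least 2 probes and 2 samples.
#' @return A symmetric sample x sample distance matrix with zero diagonal.
#' @export
spearmanDistanceMatrix <- function(x) {
    b <- if (is(x, "SummarizedExperiment")) assay(x, "beta") else x
    if (nrow(b) < 2L) stop("at least 2 probes are required")
    if (ncol(b) < 2L) stop("at least 2 samples are required")
    const <- .rowSds(t(b)) == 0
    if (any(const))
        stop("constant sample(s) with zero rank variance: ",
             paste(colnames(b)[const], collapse = ", "))
    d <- 1 - stats::cor(b, method = "spearman")
    diag(d) <- 0
    d
}
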
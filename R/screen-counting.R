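#' Count exact protospacer matches in a FASTQ file
#'
#' Assigns reads to library constructs by exact string match of the read
#' window \code{[offset + 1, offset + length]} against the first
#' \code{length} bases of \code{protospacer_a}. Reads whose window does not
#' match any protospacer (including by a single mismatch) are counted as
#' unassigned.
#'
#' @param fastq path to a FASTQ file (optionally gzipped).
#' @param library data.frame with \code{construct_id} and
#'   \code{protospacer_a} (a \linkS4class{ScreenExperiment}'s rowData works
#'   too).
#' @param offset 0-based offset of the protospacer within the read.
#' @param length length of the match window; defaults to the protospacer
#'   length.
#' @return A list with \code{counts} (named integer vector over all
#'   constructs), \code{unassigned} (count of unmatched reads), and
#'   \code{match_rate} (assigned / total; \code{NA} with a warning for an
#'   empty file).
#' @export
countProtospacers <- function(fastq, library, offset = 0L, length = NULL) {
    library <- as.data.frame(library)
    if (is.null(library$construct_id) && !is.null(rownames(library)))
        library$construct_id <- rownames(library)
    ps <- as.character(library$protospacer_a)
    if (is.null(length)) length <- min(nchar(ps))
    key <- substr(ps, 1L, length)
    if (anyDuplicated(key)) {
        dup <- unique(key[duplicated(key)])
        stop("protospacers are not unique over the first ", length,
             " bases; collisions: ", paste(head(dup, 5), collapse = ", "))
    }
    reads <- Biostrings::readDNAStringSet(fastq, format = "fastq")
    counts <- stats::setNames(integer(nrow(library)), library$construct_id)
    if (length(reads) == 0L) {
        warning("empty FASTQ: ", fastq, "; match rate undefined")
        return(list(counts = counts, unassigned = 0L, match_rate = NA_real_))
    }
    if (any(Biostrings::width(reads) < offset + length))
        stop("offset + length exceeds read length for some reads")
    win <- as.character(Biostrings::subseq(reads, start = offset + 1L,
                                           width = length))
    hit <- match(win, key)
    tab <- table(hit[!is.na(hit)])
    counts[as.integer(names(tab))] <- as.integer(tab)
    assigned <- sum(!is.na(hit))
    list(counts = counts, unassigned = length(reads) - assigned,
         match_rate = assigned / length(reads))
}

# One column of multivariate hypergeometric subsampling: draw `size` reads
# without replacement from a pool with `x[i]` copies of construct i, by
# sequential conditional hypergeometric draws.
.hyperDownsample <- function(x, size) {
    total <- sum(x)
    if (size >= total) return(x)
    out <- integer(length(x))
    left <- total
    draw <- size
    for (i in seq_along(x)) {
        if (draw == 0L) break
        xi <- x[i]
        if (xi > 0L) {
            out[i] <- stats::rhyper(1L, m = xi, n = left - xi, k = draw)
            draw <- draw - out[i]
        }
        left <- left - xi
    }
    out
}

#' Downsample all samples to a common sequencing depth
#'
#' Each sample column is subsampled without replacement (multivariate
#' hypergeometric) to the minimum column total, so that all column sums are
#' equal afterward. Columns already at the minimum are returned unchanged.
#' Draws run in canonical (sorted) construct order with one random substream
#' per sample, so the realized subsample is invariant to row and column
#' ordering of the input.
#'
#' @param x a \linkS4class{ScreenExperiment} or an integer count matrix.
#' @param seed integer seed for the subsampling.
#' @return An object of the same class as \code{x} with equalized column
#'   totals.
#' @export
downsampleToCommonDepth <- function(x, seed = 1L) {
    cts <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    totals <- colSums(cts)
    if (any(totals == 0))
        stop("sample(s) with zero total counts: ",
             paste(colnames(cts)[totals == 0], collapse = ", "))
    target <- min(totals)
    ord <- order(rownames(cts))
    out <- cts
    for (j in which(totals > target)) {
        set.seed(.substreamSeed(seed, paste0("downsample:", colnames(cts)[j])))
        out[ord, j] <- .hyperDownsample(cts[ord, j], target)
    }
    storage.mode(out) <- "integer"
    if (is(x, "SummarizedExperiment")) {
        assay(x, "counts") <- out
        metadata(x)$downsampled_to <- target
        x
    } else out
}

#' Filter constructs by mean normalized abundance
#'
#' Retains constructs whose mean count across all samples is at least
#' \code{min_mean} (default 50 normalized reads); intended to run after depth
#' equalization.
#'
#' @param x a \linkS4class{ScreenExperiment} or count matrix.
#' @param min_mean minimum mean count across all samples.
#' @return The filtered object; excluded construct ids are recorded in
#'   \code{metadata(x)$excluded_constructs} (or as attribute
#'   \code{"excluded"} for a matrix).
#' @export
filterLowAbundance <- function(x, min_mean = 50) {
    cts <- if (is(x, "SummarizedExperiment")) assay(x, "counts") else x
    keep <- rowMeans(cts) >= min_mean
    excluded <- rownames(cts)[!keep]
    if (!any(keep))
        warning("no constructs pass the mean-count filter (min_mean = ",
                min_mean, ")")
    out <- if (is(x, "SummarizedExperiment")) x[keep, ]
           else x[keep, , drop = FALSE]
    if (is(x, "SummarizedExperiment")) {
        metadata(out)$excluded_constructs <- excluded
        metadata(out)$min_mean <- min_mean
    } else attr(out, "excluded") <- excluded
    out
}
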
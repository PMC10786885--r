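#' Accessors for ConsensusResult
#'
#' \code{selectedK} returns the selected number of groups; \code{consensusK}
#' returns the vector of evaluated k; \code{consensusMatrix} extracts the
#' consensus matrix for one k; \code{groupLabels} extracts the per-sample
#' labels for one k (default: the selected k); \code{kDiagnostics} returns a
#' data.frame of A(k), delta(k) and mean silhouette per k.
#'
#' @param x a \linkS4class{ConsensusResult}.
#' @param k integer, one of the evaluated k.
#' @param ... unused.
#' @return See the description of each accessor.
#' @name ConsensusResult-accessors
NULL

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("selectedK", function(x, ...) standardGeneric("selectedK"))

#' @rdname ConsensusResult-accessors
#' @export
setMethod("selectedK", "ConsensusResult", function(x, ...) x@selectedK)

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("consensusK", function(x, ...) standardGeneric("consensusK"))

#' @rdname ConsensusResult-accessors
#' @export
setMethod("consensusK", "ConsensusResult", function(x, ...) x@ks)

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("consensusMatrix", function(x, k, ...)
    standardGeneric("consensusMatrix"))

#' @rdname ConsensusResult-accessors
#' @export
setMethod("consensusMatrix", "ConsensusResult", function(x, k, ...) {
    .checkKInRange(x, k)
    x@consensus[[as.character(k)]]
})

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("groupLabels", function(x, k, ...) standardGeneric("groupLabels"))

#' @rdname ConsensusResult-accessors
#' @export
setMethod("groupLabels", "ConsensusResult", function(x, k, ...) {
    if (missing(k)) {
        if (is.na(x@selectedK))
            stop("no selected k yet; run evaluateK() or give k explicitly")
        k <- x@selectedK
    }
    .checkKInRange(x, k)
    stats::setNames(x@labels[, as.character(k)], x@sampleIds)
})

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("kDiagnostics", function(x, ...) standardGeneric("kDiagnostics"))

#' @rdname ConsensusResult-accessors
#' @export
setMethod("kDiagnostics", "ConsensusResult", function(x, ...) {
    data.frame(k = x@ks,
               auc = if (length(x@auc)) x@auc else NA_real_,
               delta_auc = if (length(x@deltaAuc)) x@deltaAuc else NA_real_,
               mean_silhouette = if (length(x@silhouette)) x@silhouette
                                 else NA_real_)
})

.checkKInRange <- function(x, k) {
    if (length(k) != 1L || !k %in% x@ks)
        stop("k must be one of the evaluated values: ",
             paste(x@ks, collapse = ", "))
    invisible(TRUE)
}
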
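# Rank-transform each sample across probes and embed the rank vectors
# exactly (all non-null singular components kept) so that Euclidean k-means
# on the embedding equals k-means on the rank vectors themselves; Euclidean
# distance between whole-sample rank vectors is a monotone function of the
# Spearman correlation distance.
.spearmanEmbedding <- function(beta) {
    R <- apply(beta, 2L, rank)          # ranks within each sample
    X <- t(R)
    X <- sweep(X, 2L, colMeans(X))
    sv <- svd(X, nu = nrow(X), nv = 0)
    keep <- sv$d > max(sv$d) * 1e-12
    E <- sv$u[, keep, drop = FALSE] %*% diag(sv$d[keep], sum(keep))
    rownames(E) <- colnames(beta)
    E
}

#' Consensus k-means clustering over sample resamples
#'
#' For each k in \code{k_range} and each of \code{n_resamples} resamples,
#' subsamples \code{ceiling(item_fraction * n)} samples without replacement,
#' runs seeded k-means (k-means++ initialization, 10 restarts) on the
#' samples' whole-probe rank vectors -- the coordinate embedding of the
#' Spearman correlation geometry -- and records co-clustering. The consensus
#' matrix entry M(k)[i, j] is the number of resamples in which i and j were
#' clustered together divided by the number in which both were sampled
#' (diagonal set to 1). Per-k group labels come from average-linkage
#' hierarchical clustering of 1 - M(k) cut into k groups.
#'
#' @param x a \linkS4class{MethylationExperiment} or a probes x samples beta
#'   matrix (already probe-filtered and variable-probe-selected).
#' @param k_range integer vector of k to evaluate.
#' @param n_resamples number of resamples per k.
#' @param item_fraction fraction of samples drawn per resample.
#' @param seed integer seed; identical seed and input give an identical
#'   result.
#' @param nstart k-means restarts per resample.
#' @param keep_assignments when TRUE, stores the per-resample sample draws
#'   and cluster labels (for auditing/recomputation); off by default to save
#'   memory.
#' @return A \linkS4class{ConsensusResult} with consensus matrices and labels
#'   filled; run \code{\link{evaluateK}} to fill the CDF/AUC/silhouette
#'   diagnostics and select k.
#' @export
consensusCluster <- function(x, k_range = 2:8, n_resamples = 1000L,
                             item_fraction = 0.8, seed = 1L, nstart = 10L,
                             keep_assignments = FALSE) {
    b <- if (is(x, "SummarizedExperiment")) assay(x, "beta") else x
    n <- ncol(b)
    k_range <- sort(unique(as.integer(k_range)))
    if (n < max(k_range) + 1L)
        stop("need at least max(k_range) + 1 = ", max(k_range) + 1L,
             " samples, got ", n)
    if (item_fraction <= 0 || item_fraction > 1)
        stop("item_fraction must be in (0, 1]")
    m <- as.integer(ceiling(item_fraction * n))
    if (m < max(k_range))
        stop("resample size ", m, " is below max(k_range)")
    E <- .spearmanEmbedding(b)
    dataDist <- spearmanDistanceMatrix(b)
    set.seed(.substreamSeed(seed, "consensus"))
    ids <- colnames(b)
    consensus <- list()
    labels <- matrix(NA_integer_, n, length(k_range),
                     dimnames = list(ids, as.character(k_range)))
    assignments <- list()
    for (ki in seq_along(k_range)) {
        k <- k_range[ki]
        co_sampled <- matrix(0, n, n)
        co_clustered <- matrix(0, n, n)
        draws <- if (keep_assignments) vector("list", n_resamples) else NULL
        for (r in seq_len(n_resamples)) {
            idx <- sort(sample.int(n, m))
            km <- .seededKmeans(E[idx, , drop = FALSE], k, nstart = nstart)
            cl <- km$cluster
            eq <- outer(cl, cl, "==")
            co_sampled[idx, idx] <- co_sampled[idx, idx] + 1
            co_clustered[idx, idx] <- co_clustered[idx, idx] + eq
            if (keep_assignments)
                draws[[r]] <- list(idx = idx, cluster = cl)
        }
        off <- co_sampled[upper.tri(co_sampled)]
        if (any(off == 0))
            stop("some sample pairs were never co-sampled at k = ", k,
                 "; increase n_resamples")
        M <- co_clustered / co_sampled
        diag(M) <- 1
        dimnames(M) <- list(ids, ids)
        consensus[[as.character(k)]] <- M
        hc <- stats::hclust(stats::as.dist(1 - M), method = "average")
        labels[, ki] <- .canonicalizeLabels(stats::cutree(hc, k = k))
        if (keep_assignments) assignments[[as.character(k)]] <- draws
    }
    new("ConsensusResult", sampleIds = ids, ks = k_range,
        consensus = consensus, labels = labels,
        cdfGrid = numeric(), cdf = list(), auc = numeric(),
        deltaAuc = numeric(), silhouette = numeric(),
        selectedK = NA_integer_, dataDist = dataDist,
        params = list(n_resamples = as.integer(n_resamples),
                      item_fraction = item_fraction, seed = as.integer(seed),
                      nstart = as.integer(nstart), resample_size = m),
        assignments = assignments)
}

#' Evaluate cluster numbers by silhouette and consensus CDF area
#'
#' Computes, per k, the empirical CDF of the upper-triangle consensus
#' entries, its area A(k) by the trapezoid rule, the relative increment
#' \code{delta(k) = (A(k) - A(k-1)) / A(k-1)} (with \code{delta} at the
#' smallest k equal to A there), and the mean silhouette width of the
#' consensus partition on the Spearman correlation distance of the clustered
#' data. The selected k maximizes the mean silhouette (coherence of the cut
#' on the data), with ties going to the smallest k; the CDF area curve is
#' the corroborating stability diagnostic -- past a well-supported k its
#' area changes little, and the k after which the relative gain stays below
#' \code{auc_gain_threshold} is reported as \code{cdf_flat_k} in the
#' parameters. Silhouettes are taken on the data distance rather than on
#' \code{1 - M(k)} because every perfectly resampling-stable partition has a
#' consensus-distance silhouette of exactly 1, which cannot rank candidate k
#' (in lopsided cohorts both the merged and the split partition can be
#' perfectly stable).
#'
#' @param result a \linkS4class{ConsensusResult} from
#'   \code{\link{consensusCluster}}.
#' @param auc_gain_threshold relative area gain below which adding a cluster
#'   is considered uninformative (diagnostic annotation).
#' @param grid_points points of the CDF evaluation grid on [0, 1].
#' @return The \linkS4class{ConsensusResult} with \code{cdf}, \code{auc},
#'   \code{deltaAuc}, \code{silhouette} and \code{selectedK} filled.
#' @export
evaluateK <- function(result, auc_gain_threshold = 0.10, grid_points = 201L) {
    stopifnot(is(result, "ConsensusResult"))
    ks <- result@ks
    if (length(ks) < 2L) stop("at least 2 values of k must be evaluated")
    n <- length(result@sampleIds)
    if (n < 3L)
        stop("degenerate consensus: need at least 3 samples to evaluate k")
    xs <- seq(0, 1, length.out = grid_points)
    cdf <- list()
    auc <- numeric(length(ks))
    sil <- numeric(length(ks))
    for (i in seq_along(ks)) {
        M <- result@consensus[[i]]
        v <- M[upper.tri(M)]
        Fv <- stats::ecdf(v)(xs)
        cdf[[as.character(ks[i])]] <- Fv
        auc[i] <- .trapz(xs, Fv)
        labs <- result@labels[, i]
        sw <- cluster::silhouette(labs, dmatrix = result@dataDist)
        sil[i] <- if (is.matrix(sw)) mean(sw[, "sil_width"]) else NA_real_
    }
    delta <- c(auc[1], diff(auc) / head(auc, -1))
    best <- order(-sil, ks)[1]
    # smallest k after which every relative area gain stays below threshold
    flat <- which(vapply(seq_along(ks), function(i)
        i == length(ks) || all(delta[(i + 1):length(ks)] <
                               auc_gain_threshold), TRUE))
    result@cdfGrid <- xs
    result@cdf <- cdf
    result@auc <- auc
    result@deltaAuc <- delta
    result@silhouette <- sil
    result@selectedK <- ks[best]
    result@params$auc_gain_threshold <- auc_gain_threshold
    result@params$cdf_flat_k <- if (length(flat)) ks[flat[1]] else NA_integer_
    result
}

#' Extract group labels and per-sample silhouettes at a given k
#'
#' Labels are the stored hierarchical cut of the consensus matrix, with
#' deterministic group ids (ordered by cluster size descending, ties by the
#' smallest member index); silhouettes are computed on the Spearman
#' correlation distance of the clustered data, consistent with
#' \code{\link{evaluateK}}.
#'
#' @param result an evaluated \linkS4class{ConsensusResult}.
#' @param k the number of groups; defaults to the selected k.
#' @return A data.frame with \code{sample_id}, \code{group},
#'   \code{silhouette}.
#' @export
assignGroups <- function(result, k = selectedK(result)) {
    stopifnot(is(result, "ConsensusResult"))
    if (is.na(k)) stop("no k given and no selected k; run evaluateK() first")
    .checkKInRange(result, k)
    labs <- result@labels[, as.character(k)]
    sw <- cluster::silhouette(labs, dmatrix = result@dataDist)
    widths <- if (is.matrix(sw)) sw[, "sil_width"] else rep(NA_real_,
                                                            length(labs))
    data.frame(sample_id = result@sampleIds, group = as.integer(labs),
               silhouette = widths, stringsAsFactors = FALSE)
}

#' Hierarchical clustering cross-check
#'
#' Ward-linkage hierarchical clustering on the Spearman correlation distance
#' of the top \code{n_probes} most variable probes, cut into \code{k} groups;
#' reports agreement (adjusted Rand index) with a reference partition when
#' one is supplied.
#'
#' @param x a \linkS4class{MethylationExperiment} or beta matrix (filtered).
#' @param k number of groups to cut.
#' @param n_probes number of most-variable probes to use.
#' @param reference_labels optional labels (e.g. consensus groups) to compare
#'   against.
#' @return A list with \code{labels} (named integer vector, canonical ids),
#'   \code{hclust} (the dendrogram object) and \code{ari} (NA when no
#'   reference given).
#' @export
hierarchicalCheck <- function(x, k, n_probes = 5000L,
                              reference_labels = NULL) {
    sub <- selectVariableProbes(x, n_probes)
    d <- spearmanDistanceMatrix(sub)
    hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
    labs <- .canonicalizeLabels(stats::cutree(hc, k = k))
    names(labs) <- colnames(d)
    ari <- NA_real_
    if (!is.null(reference_labels)) {
        if (!is.null(names(reference_labels)))
            reference_labels <- reference_labels[names(labs)]
        ari <- .ari(labs, reference_labels)
    }
    list(labels = labs, hclust = hc, ari = ari)
}
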
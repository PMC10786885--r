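# Internal helpers shared across the two pipelines.

# Derive a reproducible 31-bit sub-seed from a root seed and a stage tag so
# that stages (simulation, downsampling, resampling, k-means) are
# independently reproducible from one root seed.
.substreamSeed <- function(seed, tag) {
    h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
    as.integer((as.numeric(seed) * 48271 + h * 2654435) %% 2147483647)
}

# Row standard deviations without loops; x is a numeric matrix.
.rowSds <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    sqrt(pmax(0, (rowSums(x * x) - n * m * m) / (n - 1)))
}

# Trapezoid rule on an ordered grid.
.trapz <- function(x, y) {
    sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
}

# k-means++ seeding: returns a k x d matrix of initial centers drawn from the
# rows of X with the classical squared-distance proposal.
.kmeansppCenters <- function(X, k) {
    n <- nrow(X)
    tX <- t(X)
    idx <- integer(k)
    idx[1] <- sample.int(n, 1L)
    d2 <- colSums((tX - X[idx[1], ])^2)
    for (j in seq_len(k - 1L) + 1L) {
        tot <- sum(d2)
        idx[j] <- if (tot <= 0) {
            sample(setdiff(seq_len(n), idx[seq_len(j - 1L)]), 1L)
        } else sample.int(n, 1L, prob = d2)
        d2 <- pmin(d2, colSums((tX - X[idx[j], ])^2))
    }
    X[idx, , drop = FALSE]
}

# Seeded k-means with k-means++ initialization and multiple restarts; keeps
# the solution with the lowest total within-cluster sum of squares.
.seededKmeans <- function(X, k, nstart = 10L, iter.max = 100L) {
    best <- NULL
    for (s in seq_len(nstart)) {
        centers <- .kmeansppCenters(X, k)
        if (anyDuplicated(centers)) {
            keep <- sample.int(nrow(X), k)
            centers <- X[keep, , drop = FALSE]
            if (anyDuplicated(centers)) next
        }
        km <- tryCatch(
            suppressWarnings(stats::kmeans(X, centers = centers,
                                           iter.max = iter.max)),
            error = function(e) NULL)
        if (!is.null(km) &&
            (is.null(best) || km$tot.withinss < best$tot.withinss))
            best <- km
    }
    if (is.null(best))
        stop("k-means failed for k = ", k,
             " (too few distinct points in the resample)")
    best
}

# Relabel an integer partition so that group 1 is the largest cluster, ties
# broken by the smallest member index; makes labels deterministic.
.canonicalizeLabels <- function(labels) {
    tab <- table(labels)
    first <- vapply(names(tab), function(l) min(which(labels == l)), 0L)
    ord <- names(tab)[order(-as.integer(tab), first)]
    as.integer(factor(as.character(labels), levels = ord))
}

# Adjusted Rand index between two partitions (delegates to mclust).
.ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Mean beta-binomial style clamp for probabilities used on the logit scale.
.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
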
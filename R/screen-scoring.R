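#' Per-replicate log2 ratios of T10 over T0 abundance
#'
#' Computes \code{L = log2((c_T10 + pseudocount) / (c_T0 + pseudocount))} for
#' every construct, arm and T10 replicate on depth-equalized counts. A single
#' baseline T0 sample serves every arm; if the sample sheet carries one T0 per
#' replicate, baselines are matched by replicate id.
#'
#' @param x a \linkS4class{ScreenExperiment}, depth-equalized (see
#'   \code{\link{downsampleToCommonDepth}}).
#' @param pseudocount added to numerator and denominator before the ratio.
#' @param arms arms to compute; defaults to every non-baseline arm present.
#' @return A list of class \code{"screenLog2Ratios"}: one constructs x
#'   replicates matrix per arm, plus attributes \code{pseudocount} and
#'   \code{is_ntc}.
#' @export
computeLog2Ratios <- function(x, pseudocount = 1, arms = NULL) {
    cd <- colData(x)
    cts <- assay(x, "counts")
    t0 <- which(cd$timepoint == "T0")
    if (length(t0) == 0L)
        stop("no T0 baseline sample present")
    if (is.null(arms))
        arms <- setdiff(unique(cd$arm), "baseline")
    if (length(arms) == 0L)
        stop("no treatment arm present (need vehicle and/or drug)")
    out <- list()
    for (arm in arms) {
        reps <- which(cd$arm == arm & cd$timepoint == "T10")
        if (length(reps) == 0L)
            stop("arm '", arm, "' has no T10 samples")
        L <- matrix(NA_real_, nrow(cts), length(reps),
                    dimnames = list(rownames(cts),
                                    colnames(cts)[reps]))
        for (i in seq_along(reps)) {
            j <- reps[i]
            j0 <- if (length(t0) == 1L) t0 else {
                hit <- t0[cd$replicate[t0] == cd$replicate[j]]
                if (length(hit) != 1L)
                    stop("no matching T0 baseline for replicate ",
                         cd$replicate[j], " of arm '", arm, "'")
                hit
            }
            L[, i] <- log2((cts[, j] + pseudocount) /
                           (cts[, j0] + pseudocount))
        }
        out[[arm]] <- L
    }
    structure(out, class = "screenLog2Ratios",
              pseudocount = pseudocount,
              is_ntc = rowData(x)$is_ntc)
}

#' Doubling- and NTC-normalized phenotype scores
#'
#' For each arm, the phenotype of a construct is its mean log2 ratio across
#' replicates, centered on the median mean log2 ratio of the non-targeting
#' controls, divided by the arm's population doublings: growth-rate effects
#' per doubling, with the NTC median exactly 0 by construction. The z score
#' standardizes the phenotype by the standard deviation of the NTC phenotypes
#' in the same arm.
#'
#' @param ratios a \code{"screenLog2Ratios"} object from
#'   \code{\link{computeLog2Ratios}}.
#' @param doublings named numeric, population doublings per arm.
#' @param is_ntc logical per construct; defaults to the flag carried by
#'   \code{ratios}.
#' @param min_ntc minimum number of NTC constructs required for the
#'   normalization to be considered reliable.
#' @return A list with \code{scores} (per-arm data.frames with
#'   \code{mean_log2fc}, \code{phenotype}, \code{z}) and \code{ntc_stats}
#'   (data.frame with one row per arm: \code{median_log2_ratio},
#'   \code{sd_phenotype}, \code{n_ntc}).
#' @export
computePhenotypeScores <- function(ratios, doublings, is_ntc = NULL,
                                   min_ntc = 10L) {
    stopifnot(inherits(ratios, "screenLog2Ratios"))
    if (is.null(is_ntc)) is_ntc <- attr(ratios, "is_ntc")
    n_ntc <- sum(is_ntc)
    if (n_ntc < min_ntc)
        stop("only ", n_ntc, " NTC constructs survive filtering; at least ",
             min_ntc, " are required for a reliable normalization")
    missing_d <- setdiff(names(ratios), names(doublings))
    if (length(missing_d))
        stop("doublings missing for arm(s): ",
             paste(missing_d, collapse = ", "))
    scores <- list()
    stats_rows <- list()
    for (arm in names(ratios)) {
        D <- doublings[[arm]]
        if (!is.finite(D) || D <= 0)
            stop("doublings for arm '", arm, "' must be > 0")
        meanL <- rowMeans(ratios[[arm]])
        ntc_med <- stats::median(meanL[is_ntc])
        phen <- (meanL - ntc_med) / D
        sd_ntc <- stats::sd(phen[is_ntc])
        if (!is.finite(sd_ntc) || sd_ntc == 0)
            stop("NTC phenotype spread is zero in arm '", arm,
                 "'; z scores are undefined")
        scores[[arm]] <- data.frame(mean_log2fc = meanL, phenotype = phen,
                                    z = phen / sd_ntc,
                                    row.names = names(meanL))
        stats_rows[[arm]] <- data.frame(arm = arm,
                                        median_log2_ratio = ntc_med,
                                        sd_phenotype = sd_ntc,
                                        n_ntc = n_ntc)
    }
    list(scores = scores,
         ntc_stats = do.call(rbind, c(stats_rows, make.row.names = FALSE)))
}

.rowVars <- function(x) {
    n <- ncol(x)
    m <- rowMeans(x)
    pmax(0, (rowSums(x * x) - n * m * m) / (n - 1))
}

# Mean-dispersion trend alpha(mu) = a0 + a1 / mu fitted by least squares with
# one outlier-trimming pass and non-negative coefficients.
.dispersionTrend <- function(alpha_mom, mu) {
    fitOnce <- function(a, m) {
        X <- cbind(1, 1 / m)
        cf <- stats::lm.fit(X, a)$coefficients
        cf[!is.finite(cf)] <- 0
        cf
    }
    cf <- fitOnce(alpha_mom, mu)
    resid <- alpha_mom - (cf[1] + cf[2] / mu)
    keep <- abs(resid) <= 3 * stats::sd(resid)
    if (sum(keep) >= 10 && any(!keep))
        cf <- fitOnce(alpha_mom[keep], mu[keep])
    a0 <- max(cf[1], 0)
    a1 <- max(cf[2], 0)
    if (a0 == 0 && a1 == 0) a0 <- max(mean(alpha_mom), 1e-8)
    pmax(a0 + a1 / mu, 1e-8)
}

#' Negative-binomial Wald test of T10 versus T0 abundance
#'
#' Per-construct two-sided Wald test from a negative-binomial log-linear
#' model of depth-equalized counts on a T10 indicator (size factors all 1
#' after depth equalization). Because the model is saturated in the two
#' groups, the maximum-likelihood group means are the sample means; the Wald
#' statistic is the log mean ratio over its standard error from the observed
#' Fisher information. Dispersion is estimated per construct by method of
#' moments across replicate groups, shrunk 50/50 toward a mean-dispersion
#' trend \code{a0 + a1/mu} fitted across all constructs. P-values are
#' adjusted across tested constructs by Benjamini-Hochberg.
#'
#' @param x a filtered, depth-equalized \linkS4class{ScreenExperiment}.
#' @param arm \code{"vehicle"} or \code{"drug"}.
#' @param shrink weight of the trend in the dispersion shrinkage (0.5 gives
#'   the 50/50 combination).
#' @return A data.frame with \code{construct_id}, \code{log2fc} (log2 ratio
#'   of group means), \code{wald}, \code{p}, \code{padj}, \code{dispersion}.
#' @export
testSignificance <- function(x, arm, shrink = 0.5) {
    cd <- colData(x)
    cts <- assay(x, "counts")
    t0 <- which(cd$timepoint == "T0")
    t10 <- which(cd$arm == arm & cd$timepoint == "T10")
    if (length(t0) == 0L) stop("no T0 baseline sample present")
    if (length(t10) == 0L) stop("arm '", arm, "' has no T10 samples")
    if (length(t10) < 2L)
        stop("dispersion cannot be estimated from a single T10 replicate; ",
             "at least 2 replicates are required")
    y0 <- cts[, t0, drop = FALSE]
    y1 <- cts[, t10, drop = FALSE]
    n0 <- ncol(y0); n1 <- ncol(y1)
    mu0 <- (rowSums(y0) + 0.5) / n0
    mu1 <- (rowSums(y1) + 0.5) / n1
    # method-of-moments dispersion pooled over groups with >= 2 replicates
    num <- rep(0, nrow(cts)); den <- rep(0, nrow(cts))
    for (grp in list(list(y = y0, mu = mu0), list(y = y1, mu = mu1))) {
        ng <- ncol(grp$y)
        if (ng >= 2L) {
            s2 <- .rowVars(grp$y)
            num <- num + (ng - 1) * (s2 - grp$mu)
            den <- den + (ng - 1) * grp$mu^2
        }
    }
    if (all(den == 0))
        stop("no replicate group with >= 2 samples; ",
             "dispersion cannot be estimated")
    alpha_mom <- pmax(num / den, 0)
    base_mu <- rowMeans(cbind(y0, y1))
    alpha_trend <- .dispersionTrend(alpha_mom, base_mu)
    alpha <- shrink * alpha_trend + (1 - shrink) * alpha_mom
    beta <- log(mu1 / mu0)
    se <- sqrt((1 + alpha * mu0) / (n0 * mu0) +
               (1 + alpha * mu1) / (n1 * mu1))
    wald <- beta / se
    p <- pmin(1, 2 * stats::pnorm(-abs(wald)))
    p <- pmax(p, .Machine$double.xmin)
    data.frame(construct_id = rownames(cts),
               log2fc = beta / log(2),
               wald = wald,
               p = p,
               padj = stats::p.adjust(p, method = "BH"),
               dispersion = alpha,
               row.names = rownames(cts))
}

.HIT_CLASSES <- c("shared_enriched", "shared_depleted",
                  "drug_selective_enriched", "drug_selective_depleted",
                  "vehicle_only_enriched", "vehicle_only_depleted",
                  "not_significant")

#' Classify constructs into shared and condition-selective hit sets
#'
#' A construct is significant in an arm when \code{padj < alpha}; its
#' direction is the sign of the arm's mean log2 fold change. Significant in
#' both arms with the same direction gives \code{shared_enriched} or
#' \code{shared_depleted}; significant in the drug arm only gives
#' \code{drug_selective_enriched}/\code{_depleted}; significant in the
#' vehicle arm only gives \code{vehicle_only_*}; otherwise
#' \code{not_significant}. The rare case of significance in both arms with
#' opposite directions is classified as drug-selective in the drug arm's
#' direction.
#'
#' @param vehicle,drug data.frames with \code{construct_id} (or rownames),
#'   a log2 fold change column (\code{mean_log2fc} or \code{log2fc}) and
#'   \code{padj}, both over the same construct set.
#' @param alpha significance threshold on the adjusted p-value.
#' @return A data.frame with \code{construct_id} and \code{hit_class}
#'   (factor over the seven classes); attribute \code{"sets"} lists the
#'   construct ids in each non-null class.
#' @export
classifyHits <- function(vehicle, drug, alpha = 0.05) {
    getCol <- function(d, what) {
        d <- as.data.frame(d)
        if (is.null(d$construct_id)) d$construct_id <- rownames(d)
        fc <- if ("mean_log2fc" %in% names(d)) d$mean_log2fc else d$log2fc
        if (is.null(fc)) stop("need a mean_log2fc or log2fc column")
        data.frame(construct_id = d$construct_id, fc = fc, padj = d$padj)
    }
    v <- getCol(vehicle); d <- getCol(drug)
    if (!setequal(v$construct_id, d$construct_id)) {
        only_v <- setdiff(v$construct_id, d$construct_id)
        only_d <- setdiff(d$construct_id, v$construct_id)
        stop("construct sets differ between arms; vehicle-only: ",
             paste(head(only_v, 5), collapse = ", "), "; drug-only: ",
             paste(head(only_d, 5), collapse = ", "))
    }
    d <- d[match(v$construct_id, d$construct_id), ]
    sig_v <- v$padj < alpha
    sig_d <- d$padj < alpha
    dir_v <- sign(v$fc)
    dir_d <- sign(d$fc)
    cls <- rep("not_significant", nrow(v))
    cls[sig_v & !sig_d & dir_v > 0] <- "vehicle_only_enriched"
    cls[sig_v & !sig_d & dir_v < 0] <- "vehicle_only_depleted"
    cls[sig_d & !sig_v & dir_d > 0] <- "drug_selective_enriched"
    cls[sig_d & !sig_v & dir_d < 0] <- "drug_selective_depleted"
    cls[sig_v & sig_d & dir_v == dir_d & dir_d > 0] <- "shared_enriched"
    cls[sig_v & sig_d & dir_v == dir_d & dir_d < 0] <- "shared_depleted"
    opp <- sig_v & sig_d & dir_v != dir_d
    cls[opp & dir_d > 0] <- "drug_selective_enriched"
    cls[opp & dir_d < 0] <- "drug_selective_depleted"
    out <- data.frame(construct_id = v$construct_id,
                      hit_class = factor(cls, levels = .HIT_CLASSES))
    sets <- split(out$construct_id, out$hit_class)
    attr(out, "sets") <- sets[setdiff(names(sets), "not_significant")]
    out
}

#' Collapse screen results to gene level
#'
#' For libraries with one construct per gene this is the identity (minus
#' NTC constructs). When a gene carries several constructs, the construct
#' with the largest absolute z score across arms represents the gene, and a
#' note reports how many genes were aggregated.
#'
#' @param results a \linkS4class{ScreenResults} table.
#' @return The results restricted to one representative row per gene,
#'   NTC constructs dropped.
#' @export
geneLevelResults <- function(results) {
    keep <- !results$is_ntc
    res <- results[keep, ]
    zcols <- grep("_z$", colnames(res), value = TRUE)
    score <- do.call(pmax, c(lapply(zcols, function(cc) abs(res[[cc]])),
                             na.rm = TRUE))
    ord <- order(res$gene, -score)
    res <- res[ord, ]
    dup <- duplicated(res$gene)
    if (any(dup))
        message(sum(dup), " extra construct(s) across ",
                length(unique(res$gene[dup])),
                " gene(s) aggregated by maximal |z|")
    res[!dup, ]
}

#' Essential-gene depletion quality control
#'
#' Counts, within a set of core essential genes, the constructs significantly
#' depleted or enriched in an arm; a healthy growth screen depletes essential
#' genes overwhelmingly. The verdict passes when depleted constructs exceed
#' \code{ratio_threshold} times the enriched ones.
#'
#' @param results a data.frame with \code{gene}, an arm's log2 fold change
#'   (\code{mean_log2fc} or \code{log2fc}) and \code{padj}; e.g. one arm's
#'   slice of \code{\link{scoreScreen}} output.
#' @param essential_genes character vector of essential gene symbols.
#' @param alpha significance threshold; \code{alpha >= 1} counts every tested
#'   construct as significant (pure sign split).
#' @param ratio_threshold pass when \code{n_depleted > ratio_threshold *
#'   n_enriched}.
#' @return A list with \code{n_essential_tested}, \code{n_depleted},
#'   \code{n_enriched}, \code{alpha}, \code{pass}.
#' @export
qcEssentialDepletion <- function(results, essential_genes, alpha = 0.05,
                                 ratio_threshold = 10) {
    results <- as.data.frame(results)
    if (length(essential_genes) == 0L)
        stop("essential gene set is empty")
    hit <- results$gene %in% essential_genes
    if (!any(hit))
        stop("essential gene set does not intersect the tested library")
    fc <- if ("mean_log2fc" %in% names(results)) results$mean_log2fc
          else results$log2fc
    padj <- results$padj
    sig <- if (alpha >= 1) rep(TRUE, nrow(results)) else padj < alpha
    n_dep <- sum(hit & sig & fc < 0)
    n_enr <- sum(hit & sig & fc > 0)
    list(n_essential_tested = sum(hit), n_depleted = n_dep,
         n_enriched = n_enr, alpha = alpha,
         pass = n_dep > ratio_threshold * n_enr)
}

#' Results table of a scored screen
#'
#' A \linkS4class{DataFrame} subclass holding one row per tested construct
#' with per-arm log2 fold changes, phenotype scores, z scores, Wald p-values
#' and adjusted p-values, and the hit class. Metadata carries the NTC
#' normalization statistics, the population doublings, and run parameters.
#'
#' @aliases ScreenResults-class
#' @exportClass ScreenResults
setClass("ScreenResults", contains = "DFrame")

setMethod("show", "ScreenResults", function(object) {
    cat("ScreenResults:", nrow(object), "constructs\n")
    cat("hit classes:\n")
    print(table(object$hit_class))
    ns <- metadata(object)$ntc_stats
    if (!is.null(ns)) {
        cat("NTC normalization:\n")
        print(ns, row.names = FALSE)
    }
    invisible(object)
})

#' Score a dual-condition CRISPRi screen end to end
#'
#' Runs the full scoring chain in order: depth equalization by hypergeometric
#' downsampling, mean-count filtering, per-replicate log2 ratios, doubling-
#' and NTC-normalized phenotype scores, per-arm negative-binomial Wald tests
#' with BH adjustment, and hit classification.
#'
#' @param x a \linkS4class{ScreenExperiment} with a baseline and at least one
#'   of the vehicle/drug arms (both are needed for hit classification).
#' @param doublings named numeric, population doublings per arm. No realized
#'   doubling count ships with the package; the value used is recorded in the
#'   result metadata.
#' @param alpha significance threshold for hit classification.
#' @param min_mean mean-count filter threshold.
#' @param pseudocount pseudocount for log2 ratios.
#' @param min_ntc minimum surviving NTC constructs.
#' @param seed seed for the downsampling.
#' @return A \linkS4class{ScreenResults} DataFrame.
#' @examples
#' sim <- simulateScreen(ScreenSimConfig(n_genes = 120, n_ntc_pairs = 30,
#'                                       seed = 2))
#' res <- scoreScreen(sim$experiment)
#' table(res$hit_class)
#' @export
scoreScreen <- function(x, doublings = c(vehicle = 8, drug = 6),
                        alpha = 0.05, min_mean = 50, pseudocount = 1,
                        min_ntc = 10L, seed = 1L) {
    x <- downsampleToCommonDepth(x, seed = seed)
    x <- filterLowAbundance(x, min_mean = min_mean)
    ratios <- computeLog2Ratios(x, pseudocount = pseudocount)
    phen <- computePhenotypeScores(ratios, doublings, min_ntc = min_ntc)
    arms <- names(ratios)
    tests <- lapply(arms, function(a) testSignificance(x, a))
    names(tests) <- arms
    tab <- DataFrame(gene = rowData(x)$gene, is_ntc = rowData(x)$is_ntc,
                     mean_count = rowMeans(assay(x, "counts")),
                     row.names = rownames(x))
    for (a in arms) {
        s <- phen$scores[[a]]
        tab[[paste0(a, "_log2fc")]] <- s$mean_log2fc
        tab[[paste0(a, "_phenotype")]] <- s$phenotype
        tab[[paste0(a, "_z")]] <- s$z
        tab[[paste0(a, "_p")]] <- tests[[a]]$p
        tab[[paste0(a, "_padj")]] <- tests[[a]]$padj
    }
    if (all(c("vehicle", "drug") %in% arms)) {
        hits <- classifyHits(
            data.frame(construct_id = rownames(tab),
                       mean_log2fc = tab$vehicle_log2fc,
                       padj = tab$vehicle_padj),
            data.frame(construct_id = rownames(tab),
                       mean_log2fc = tab$drug_log2fc,
                       padj = tab$drug_padj),
            alpha = alpha)
        tab$hit_class <- hits$hit_class
        sets <- attr(hits, "sets")
    } else sets <- NULL
    res <- new("ScreenResults", tab)
    metadata(res) <- list(ntc_stats = phen$ntc_stats, doublings = doublings,
                          alpha = alpha, min_mean = min_mean,
                          pseudocount = pseudocount, seed = seed,
                          excluded_constructs =
                              metadata(x)$excluded_constructs,
                          hit_sets = sets)
    res
}
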
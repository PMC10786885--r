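twoBlockSim <- function(seed = 2) {
    simulateMethylation(MethSimConfig(
        group_sizes = c(6L, 6L), n_probes = 400L,
        n_informative_per_group = 60L, beta_shift = 0.4,
        sample_noise_sd = 0.05,
        n_flagged = c(sex_chrom = 10L, snp_overlap = 5L, multimap = 5L,
                      detection_fail = 5L), seed = seed))
}

test_that("consensus matrices satisfy their contract and are seeded", {
    sim <- twoBlockSim()
    se <- filterProbes(sim$experiment)
    res1 <- consensusCluster(se, k_range = 2:4, n_resamples = 50, seed = 7)
    res2 <- consensusCluster(se, k_range = 2:4, n_resamples = 50, seed = 7)
    for (k in 2:4) {
        M <- consensusMatrix(res1, k)
        expect_equal(M, t(M))
        expect_true(all(diag(M) == 1))
        expect_gte(min(M), 0)
        expect_lte(max(M), 1)
        expect_identical(M, consensusMatrix(res2, k))
    }
    expect_identical(res1@labels, res2@labels)
})

test_that("well-separated blocks give a near-binary consensus at k = 2", {
    sim <- twoBlockSim()
    se <- filterProbes(sim$experiment)
    res <- consensusCluster(se, k_range = 2:4, n_resamples = 200, seed = 1)
    M <- consensusMatrix(res, 2)
    grp <- sim$truth$samples$group
    within <- M[outer(grp, grp, "==") & upper.tri(M)]
    between <- M[outer(grp, grp, "!=") & upper.tri(M)]
    expect_gt(min(within), 0.95)
    expect_lt(max(between), 0.05)
    res <- evaluateK(res)
    expect_identical(selectedK(res), 2L)
    expect_gt(res@silhouette[1], 0.9)
    # CDF of a near-binary consensus is flat between its two steps
    cdf2 <- res@cdf[["2"]]
    expect_true(all(diff(cdf2) >= 0))
    expect_equal(cdf2[length(cdf2)], 1)
    mid <- res@cdfGrid > 0.1 & res@cdfGrid < 0.9
    expect_lt(max(cdf2[mid]) - min(cdf2[mid]), 0.02)
    # groups reproduce the planted blocks exactly
    g <- assignGroups(res, 2)
    expect_equal(mclust::adjustedRandIndex(g$group, grp), 1)
})

test_that("consensus CDF is non-decreasing and reaches 1 for every k", {
    sim <- twoBlockSim(seed = 5)
    se <- filterProbes(sim$experiment)
    res <- evaluateK(consensusCluster(se, 2:5, n_resamples = 60, seed = 3))
    for (k in as.character(2:5)) {
        Fv <- res@cdf[[k]]
        expect_true(all(diff(Fv) >= 0))
        expect_equal(Fv[length(Fv)], 1)
    }
    expect_true(all(res@auc >= 0 & res@auc <= 1))
})

test_that("consensus matrix equals brute-force recomputation exactly", {
    sim <- simulateMethylation(MethSimConfig(
        group_sizes = c(7L, 5L), n_probes = 50L,
        n_informative_per_group = 10L,
        n_flagged = c(sex_chrom = 2L, snp_overlap = 2L, multimap = 2L,
                      detection_fail = 1L), seed = 4))
    beta <- SummarizedExperiment::assay(sim$experiment, "beta")
    res <- consensusCluster(beta, k_range = 2:3, n_resamples = 20,
                            seed = 11, keep_assignments = TRUE)
    for (k in 2:3) {
        M_oracle <- consensusOracle(res@assignments[[as.character(k)]],
                                    n = ncol(beta))
        dimnames(M_oracle) <- dimnames(consensusMatrix(res, k))
        expect_identical(consensusMatrix(res, k), M_oracle)
    }
})

test_that("grouping is invariant to sample permutation", {
    sim <- twoBlockSim(seed = 8)
    se <- filterProbes(sim$experiment)
    beta <- SummarizedExperiment::assay(se, "beta")
    perm <- sample(ncol(beta))
    res1 <- evaluateK(consensusCluster(beta, 2:4, n_resamples = 100,
                                       seed = 2))
    res2 <- evaluateK(consensusCluster(beta[, perm], 2:4, n_resamples = 100,
                                       seed = 2))
    expect_identical(selectedK(res1), selectedK(res2))
    g1 <- assignGroups(res1)
    g2 <- assignGroups(res2)
    g2 <- g2[match(g1$sample_id, g2$sample_id), ]
    expect_equal(mclust::adjustedRandIndex(g1$group, g2$group), 1)
})

test_that("planted partition beats random partitions on silhouette", {
    sim <- twoBlockSim(seed = 6)
    se <- filterProbes(sim$experiment)
    d <- spearmanDistanceMatrix(se)
    grp <- sim$truth$samples$group
    silOf <- function(labels)
        mean(cluster::silhouette(labels, dmatrix = d)[, "sil_width"])
    s_true <- silOf(grp)
    set.seed(1)
    s_rand <- replicate(100, silOf(sample(grp)))
    expect_true(all(s_true >= s_rand))
})

test_that("too few resamples or samples fail with actionable errors", {
    sim <- twoBlockSim(seed = 3)
    beta <- SummarizedExperiment::assay(sim$experiment, "beta")
    expect_error(consensusCluster(beta, k_range = 2:3, n_resamples = 1,
                                  item_fraction = 0.5, seed = 1),
                 "n_resamples")
    expect_error(consensusCluster(beta[, 1:5], k_range = 2:8, seed = 1),
                 "at least")
    res <- consensusCluster(beta, 2:3, n_resamples = 30, seed = 1)
    expect_error(consensusMatrix(res, 7), "evaluated")
    expect_error(assignGroups(res, 7), "evaluated")
    expect_error(assignGroups(res), "evaluateK")
})

test_that("Ward hierarchical clustering cross-checks the consensus groups", {
    sim <- twoBlockSim(seed = 12)
    se <- filterProbes(sim$experiment)
    grp <- sim$truth$samples$group
    hc <- hierarchicalCheck(se, k = 2, n_probes = 100,
                            reference_labels = grp)
    expect_equal(mclust::adjustedRandIndex(hc$labels, grp), 1)
    expect_equal(hc$ari, 1)
    one <- SummarizedExperiment::assay(se, "beta")[1, , drop = FALSE]
    suppressWarnings(expect_error(hierarchicalCheck(one, k = 2, n_probes = 2),
                                  "at least 2 probes"))
})
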
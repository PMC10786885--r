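test_that("log2 ratios follow the closed form with pseudocounts", {
    cts <- matrix(c(100L, 40L, 0L,    # T0
                    100L, 80L, 31L,   # vehicle rep 1
                    100L, 80L, 31L),  # drug rep 1
                  nrow = 3,
                  dimnames = list(c("c1", "c2", "c3"), c("t0", "v1", "d1")))
    se <- toyScreenExperiment(cts, is_ntc = c(FALSE, FALSE, FALSE),
                              arm = c("baseline", "vehicle", "drug"),
                              timepoint = c("T0", "T10", "T10"),
                              replicate = c(1L, 1L, 1L))
    r <- computeLog2Ratios(se, pseudocount = 1)
    expect_equal(r$vehicle["c1", 1], log2(101 / 101))          # equal -> 0
    expect_equal(r$vehicle["c2", 1], log2(81 / 41))            # ~doubled
    expect_equal(r$vehicle["c3", 1], 5)                        # log2(32/1)
    # exactly doubled counts give exactly 1 without pseudocount
    r0 <- computeLog2Ratios(se, pseudocount = 0)
    expect_equal(r0$vehicle["c2", 1], 1)
    expect_error(computeLog2Ratios(se, arms = "mock"), "mock")
})

test_that("missing baseline or arm is reported by name", {
    cts <- matrix(c(10L, 10L), 1, dimnames = list("c1", c("v1", "v2")))
    se <- toyScreenExperiment(cts, is_ntc = FALSE,
                              arm = c("vehicle", "vehicle"),
                              timepoint = c("T10", "T10"),
                              replicate = 1:2)
    expect_error(computeLog2Ratios(se), "T0")
})

test_that("phenotype and z match the hand-computed toy oracle", {
    # NTC mean ratios {-0.1, 0, 0.1}, target ratio 1.6, D = 8:
    # phenotype = (1.6 - 0)/8 = 0.2; NTC phenotypes {-0.0125, 0, 0.0125},
    # z = 0.2 / sd = 0.2 / 0.0125 = 16
    L <- matrix(c(-0.1, 0, 0.1, 1.6), ncol = 1,
                dimnames = list(c("n1", "n2", "n3", "tgt"), "v1"))
    ratios <- structure(list(vehicle = L), class = "screenLog2Ratios",
                        pseudocount = 1,
                        is_ntc = c(TRUE, TRUE, TRUE, FALSE))
    ph <- computePhenotypeScores(ratios, c(vehicle = 8), min_ntc = 3)
    expect_equal(ph$scores$vehicle["tgt", "phenotype"], 0.2)
    expect_equal(ph$scores$vehicle["tgt", "z"],
                 0.2 / stats::sd(c(-0.0125, 0, 0.0125)))
    expect_equal(ph$ntc_stats$median_log2_ratio, 0)
    expect_equal(ph$ntc_stats$n_ntc, 3L)
    # a construct at the NTC median has phenotype and z exactly 0
    expect_equal(ph$scores$vehicle["n2", "z"], 0)
    # doubling the doublings halves the phenotype
    ph4 <- computePhenotypeScores(ratios, c(vehicle = 4), min_ntc = 3)
    expect_equal(ph4$scores$vehicle["tgt", "phenotype"], 0.4)
    # the default contract refuses fewer than 10 NTCs
    expect_error(computePhenotypeScores(ratios, c(vehicle = 8)),
                 "at least 10")
})

test_that("phenotype and z agree with an independent script to 1e-12", {
    set.seed(42)
    n <- 20
    cts <- matrix(rpois(n * 7, lambda = 400), n,
                  dimnames = list(sprintf("c%02d", 1:n),
                                  c("t0", paste0("v", 1:3), paste0("d", 1:3))))
    storage.mode(cts) <- "integer"
    is_ntc <- c(rep(TRUE, 10), rep(FALSE, 10))
    se <- toyScreenExperiment(cts, is_ntc = is_ntc)
    ratios <- computeLog2Ratios(se, pseudocount = 1)
    ph <- computePhenotypeScores(ratios, c(vehicle = 8, drug = 6))
    oracle_v <- phenotypeOracle(cts, t10_cols = 2:4, t0_col = 1,
                                is_ntc = is_ntc, D = 8)
    oracle_d <- phenotypeOracle(cts, t10_cols = 5:7, t0_col = 1,
                                is_ntc = is_ntc, D = 6)
    expect_equal(ph$scores$vehicle$phenotype, oracle_v$phenotype,
                 tolerance = 1e-12)
    expect_equal(ph$scores$vehicle$z, oracle_v$z, tolerance = 1e-12)
    expect_equal(ph$scores$drug$phenotype, oracle_d$phenotype,
                 tolerance = 1e-12)
    expect_equal(ph$scores$drug$z, oracle_d$z, tolerance = 1e-12)
})

test_that("Wald test respects BH structure and replicate requirements", {
    sim <- defaultScreenSim()
    se <- filterLowAbundance(downsampleToCommonDepth(sim$experiment), 50)
    tt <- testSignificance(se, "vehicle")
    expect_true(all(tt$padj >= tt$p))
    ord <- order(tt$p)
    expect_true(all(diff(cummin(rev(tt$padj[ord]))) <= 0))  # monotone step-up
    expect_true(all(tt$p > 0 & tt$p <= 1))
    # single replicate cannot support dispersion estimation
    se1 <- se[, c("T0", "vehicle_T10_1")]
    expect_error(testSignificance(se1, "vehicle"), "at least 2 replicates")
})

test_that("planted fitness suppressors reach significance in vehicle", {
    sim <- defaultScreenSim()
    res <- defaultScreenResults()
    sup <- sim$truth$construct_id[sim$truth$class == "fitness_suppressor"]
    sup <- intersect(sup, rownames(res))
    expect_gte(mean(res[sup, "vehicle_padj"] < 0.05), 0.9)
    expect_true(all(res[sup, "vehicle_log2fc"] > 0))
})

test_that("hit classes follow the two-arm significance and direction rules", {
    # log2 FC / padj pairs from the three canonical worked examples
    veh <- data.frame(construct_id = c("NF2", "KRAS", "RB1"),
                      mean_log2fc = c(3.57, -0.63, 1.01),
                      padj = c(8.10e-86, 0.38, 0.24))
    drg <- data.frame(construct_id = c("NF2", "KRAS", "RB1"),
                      mean_log2fc = c(2.18, -2.12, 1.66),
                      padj = c(6.33e-31, 1e-4, 0.04))
    cls <- classifyHits(veh, drg, alpha = 0.05)
    expect_identical(as.character(cls$hit_class),
                     c("shared_enriched", "drug_selective_depleted",
                       "drug_selective_enriched"))
    sets <- attr(cls, "sets")
    expect_identical(sets$shared_enriched, "NF2")
    # mismatched construct sets fail with the symmetric difference
    expect_error(classifyHits(veh[-1, ], drg, alpha = 0.05), "KRAS|NF2")
})

test_that("essential-gene QC counts depletion and handles alpha = 1", {
    sim <- defaultScreenSim()
    res <- defaultScreenResults()
    truth <- sim$truth
    ess_genes <- truth$gene[truth$class == "essential"]
    slice <- data.frame(gene = res$gene, mean_log2fc = res$vehicle_log2fc,
                        padj = res$vehicle_padj)
    qc <- qcEssentialDepletion(slice, ess_genes, alpha = 0.05)
    expect_gte(qc$n_depleted / qc$n_essential_tested, 0.8)
    expect_lte(qc$n_enriched, 0.05 * qc$n_essential_tested)
    expect_true(qc$pass)
    qc1 <- qcEssentialDepletion(slice, ess_genes, alpha = 1.0)
    expect_identical(qc1$n_depleted + qc1$n_enriched,
                     qc1$n_essential_tested)
    expect_error(qcEssentialDepletion(slice, c("NOPE1", "NOPE2")),
                 "does not intersect")
})

test_that("scoring is invariant to construct order and centers NTCs", {
    cfg <- ScreenSimConfig(n_genes = 150, n_ntc_pairs = 30, seed = 13)
    sim <- simulateScreen(cfg)
    se <- sim$experiment
    perm <- sample(nrow(se))
    res1 <- scoreScreen(se)
    res2 <- scoreScreen(se[perm, ])
    expect_identical(rownames(res2), rownames(se)[perm][
        rownames(se)[perm] %in% rownames(res2)])
    common <- intersect(rownames(res1), rownames(res2))
    expect_equal(as.data.frame(res1[common, ]),
                 as.data.frame(res2[common, ]))
    # NTC median phenotype is zero by centering (floating-point exact up to
    # the rounding of the even-count median)
    ntc <- res1$is_ntc
    expect_lt(abs(stats::median(res1$vehicle_phenotype[ntc])), 1e-12)
    expect_lt(abs(stats::median(res1$drug_phenotype[ntc])), 1e-12)
})

test_that("gene-level aggregation keeps the construct of maximal |z|", {
    res <- defaultScreenResults()
    g1 <- geneLevelResults(res)
    expect_false(any(g1$is_ntc))
    expect_identical(nrow(g1), length(unique(res$gene[!res$is_ntc])))
    # duplicate a gene across two constructs with differing |z|
    dup <- res[1:2, ]
    dup$gene <- "SAMEGENE"
    rownames(dup) <- c("dupA", "dupB")
    dup$drug_z <- c(1, -5)
    dup$vehicle_z <- c(0.5, 0.2)
    combined <- rbind(res, dup)
    expect_message(g2 <- geneLevelResults(combined), "aggregated")
    expect_identical(rownames(g2)[g2$gene == "SAMEGENE"], "dupB")
})
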
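screenInputDir <- function(seed = 21, dir = tempfile("screen")) {
    sim <- simulateScreen(ScreenSimConfig(n_genes = 120, n_ntc_pairs = 30,
                                          seed = seed))
    writeScreenInputs(sim, dir)
    dir
}

methInputDir <- function(seed = 2, dir = tempfile("meth")) {
    sim <- simulateMethylation(MethSimConfig(
        group_sizes = c(6L, 6L), n_probes = 400L,
        n_informative_per_group = 60L,
        n_flagged = c(sex_chrom = 10L, snp_overlap = 5L, multimap = 5L,
                      detection_fail = 5L), seed = seed))
    writeMethylationInputs(sim, dir)
    dir
}

test_that("the screen orchestrator produces a complete, reproducible run", {
    dir <- screenInputDir()
    out1 <- file.path(dir, "out1")
    cfg <- list(counts = file.path(dir, "counts.tsv"),
                library = file.path(dir, "library.tsv"),
                samples = file.path(dir, "samples.csv"),
                out = out1, seed = 5)
    r1 <- suppressMessages(runScreen(cfg))
    expect_identical(r1$status, 0L)
    expect_true(all(file.exists(file.path(out1, c("results.tsv",
                                                  "summary.json",
                                                  "config.yaml")))))
    tsv <- read.delim(file.path(out1, "results.tsv"))
    expect_identical(nrow(tsv), nrow(r1$results))
    expect_identical(nrow(tsv),
                     150L - r1$summary$n_excluded)
    # identical config and seed reproduce summary.json byte for byte
    cfg$out <- file.path(dir, "out2")
    r2 <- suppressMessages(runScreen(cfg))
    expect_identical(readLines(file.path(out1, "summary.json")),
                     readLines(file.path(cfg$out, "summary.json")))
})

test_that("screen orchestrator errors name missing inputs and arms", {
    dir <- screenInputDir(seed = 22)
    cfg <- list(counts = file.path(dir, "counts.tsv"),
                library = file.path(dir, "library.tsv"),
                samples = file.path(dir, "samples.csv"),
                out = file.path(dir, "out"))
    # a sample sheet without the drug arm
    sheet <- read.csv(cfg$samples)
    novel <- file.path(dir, "samples_nodrug.csv")
    write.csv(sheet[sheet$arm != "drug", ], novel, row.names = FALSE)
    cfg_bad <- cfg; cfg_bad$samples <- novel
    expect_error(runScreen(cfg_bad), "drug")
    cfg_bad2 <- cfg; cfg_bad2$counts <- file.path(dir, "nope.tsv")
    expect_error(runScreen(cfg_bad2), "not found")
    expect_error(runScreen(c(cfg, list(mystery = 1))), "mystery")
    expect_error(runScreen(cfg[names(cfg) != "library"]), "library")
})

test_that("the methylation orchestrator writes labels and diagnostics", {
    dir <- methInputDir()
    cfg <- list(beta = file.path(dir, "beta.tsv"),
                detp = file.path(dir, "detp.tsv"),
                probes = file.path(dir, "probes.tsv"),
                out = file.path(dir, "out"),
                k_min = 2, k_max = 4, n_probes = 200, resamples = 100,
                hierarchical_probes = 100, seed = 3)
    r <- suppressMessages(runMethylationGrouping(cfg))
    expect_identical(r$status, 0L)
    labs <- read.delim(file.path(cfg$out, "labels.tsv"))
    expect_identical(nrow(labs), 12L)      # one row per sample
    expect_identical(r$summary$selected_k, 2L)
    expect_true(file.exists(file.path(cfg$out, "consensus_k2.tsv")))
    smry <- jsonlite::read_json(file.path(cfg$out, "summary.json"))
    expect_equal(smry$selected_k, 2)
    expect_equal(smry$probe_filter$retained, 375)  # 400 - 25 planted flags
})

test_that("methylation orchestrator validates inputs before running", {
    dir <- methInputDir(seed = 4)
    cfg <- list(beta = file.path(dir, "beta.tsv"),
                detp = file.path(dir, "detp.tsv"),
                probes = file.path(dir, "probes.tsv"),
                out = file.path(dir, "out"), k_min = 2, k_max = 4,
                n_probes = 200, resamples = 50, seed = 1)
    # an out-of-range beta value is rejected citing probe and sample
    beta <- readBetaMatrix(cfg$beta)
    bad <- beta
    bad[3, 2] <- 1.2
    badfile <- file.path(dir, "beta_bad.tsv")
    data.table::fwrite(data.frame(probe_id = rownames(bad), bad,
                                  check.names = FALSE), badfile, sep = "\t")
    cfg_bad <- cfg; cfg_bad$beta <- badfile
    expect_error(runMethylationGrouping(cfg_bad), rownames(bad)[3])
    # k_max must leave more samples than clusters
    cfg_k <- cfg; cfg_k$k_max <- 12
    expect_error(runMethylationGrouping(cfg_k), "n_samples - 1")
})
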
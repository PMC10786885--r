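# Independent oracles used across test files. These are deliberately naive
# (plain loops, closed forms) and share no code with the package internals.

# Rank-sum AUROC of scores for positives vs negatives.
aurocOracle <- function(pos, neg) {
    r <- rank(c(pos, neg))
    (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
        (length(pos) * length(neg))
}

# Hand-coded phenotype/z computation: per-construct mean log2 ratio against a
# shared T0 column, NTC-median centering, per-doubling scaling, NTC-sd
# standardization. Loops on purpose.
phenotypeOracle <- function(counts, t10_cols, t0_col, is_ntc, D,
                            pseudocount = 1) {
    n <- nrow(counts)
    meanL <- numeric(n)
    for (i in seq_len(n)) {
        ls <- numeric(0)
        for (j in t10_cols)
            ls <- c(ls, log2((counts[i, j] + pseudocount) /
                             (counts[i, t0_col] + pseudocount)))
        meanL[i] <- mean(ls)
    }
    med <- stats::median(meanL[is_ntc])
    phen <- (meanL - med) / D
    z <- phen / stats::sd(phen[is_ntc])
    list(mean_log2fc = meanL, phenotype = phen, z = z)
}

# Brute-force consensus matrix from stored resample draws: independent double
# loop over co-sampled pairs.
consensusOracle <- function(draws, n) {
    I <- matrix(0, n, n)
    C <- matrix(0, n, n)
    for (d in draws) {
        idx <- d$idx
        cl <- d$cluster
        for (a in seq_along(idx)) {
            for (b in seq_along(idx)) {
                I[idx[a], idx[b]] <- I[idx[a], idx[b]] + 1
                if (cl[a] == cl[b])
                    C[idx[a], idx[b]] <- C[idx[a], idx[b]] + 1
            }
        }
    }
    M <- C / I
    diag(M) <- 1
    M
}

# Tiny ScreenExperiment built by hand around a given count matrix.
toyScreenExperiment <- function(counts, is_ntc,
                                arm = NULL, timepoint = NULL,
                                replicate = NULL) {
    n <- nrow(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- sprintf("c%02d", seq_len(n))
    lib <- data.frame(construct_id = rownames(counts),
                      gene = ifelse(is_ntc, "NTC",
                                    paste0("G", seq_len(n))),
                      protospacer_a = sprintf("AAAAAAAAAAAAAAAAAA%02d",
                                              seq_len(n)),
                      protospacer_b = sprintf("CCCCCCCCCCCCCCCCCC%02d",
                                              seq_len(n)),
                      is_ntc = is_ntc)
    if (is.null(arm)) {
        m <- ncol(counts)
        stopifnot(m >= 3)
        nrep <- (m - 1) / 2
        arm <- c("baseline", rep("vehicle", nrep), rep("drug", nrep))
        timepoint <- c("T0", rep("T10", m - 1))
        replicate <- c(1L, seq_len(nrep), seq_len(nrep))
    }
    if (is.null(colnames(counts)))
        colnames(counts) <- paste0(arm, "_", timepoint, "_", replicate)
    sheet <- data.frame(sample_id = colnames(counts), arm = arm,
                        timepoint = timepoint, replicate = replicate)
    ScreenExperiment(counts, lib, sheet)
}

# Cache for the default methylation cohort simulation (seed 1), reused by
# several test files to avoid regenerating 20000 x 119 matrices.
.simCache <- new.env(parent = emptyenv())
defaultMethSim <- function() {
    if (is.null(.simCache$meth))
        .simCache$meth <- simulateMethylation(MethSimConfig(seed = 1))
    .simCache$meth
}
defaultScreenSim <- function() {
    if (is.null(.simCache$screen))
        .simCache$screen <- simulateScreen(ScreenSimConfig(seed = 7))
    .simCache$screen
}
defaultScreenResults <- function() {
    if (is.null(.simCache$screen_res))
        .simCache$screen_res <- scoreScreen(defaultScreenSim()$experiment)
    .simCache$screen_res
}
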
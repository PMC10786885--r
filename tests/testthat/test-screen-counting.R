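writeFastq <- function(reads, path) {
    lines <- unlist(lapply(seq_along(reads), function(i)
        c(paste0("@read", i), reads[i], "+",
          strrep("I", nchar(reads[i])))))
    writeLines(lines, path)
    path
}

test_that("protospacer counting is exact-match with an unassigned tally", {
    lib <- data.frame(construct_id = c("A", "B"),
                      protospacer_a = c("ACGTACGTAC", "TTTTGGGGCC"))
    fq <- writeFastq(c("ACGTACGTACAAAA", "ACGTACGTACTTTT",
                       "TTTTGGGGCCAAAA"), tempfile(fileext = ".fastq"))
    res <- countProtospacers(fq, lib, offset = 0, length = 10)
    expect_identical(res$counts, c(A = 2L, B = 1L))
    expect_identical(res$unassigned, 0L)
    expect_equal(res$match_rate, 1.0)

    # one mismatch in the window -> unassigned
    fq2 <- writeFastq(c("ACGTACGTAGAAAA"), tempfile(fileext = ".fastq"))
    res2 <- countProtospacers(fq2, lib, offset = 0, length = 10)
    expect_identical(sum(res2$counts), 0L)
    expect_identical(res2$unassigned, 1L)

    # offset shifts the window
    fq3 <- writeFastq(c("NNACGTACGTACAA"), tempfile(fileext = ".fastq"))
    res3 <- countProtospacers(fq3, lib, offset = 2, length = 10)
    expect_identical(res3$counts[["A"]], 1L)
})

test_that("empty FASTQ yields a zero column and undefined match rate", {
    lib <- data.frame(construct_id = "A", protospacer_a = "ACGTACGTAC")
    fq <- tempfile(fileext = ".fastq")
    writeLines(character(0), fq)
    expect_warning(res <- countProtospacers(fq, lib, 0, 10), "empty FASTQ")
    expect_identical(res$counts, c(A = 0L))
    expect_true(is.na(res$match_rate))
})

test_that("duplicate protospacers at the match window are a config error", {
    lib <- data.frame(construct_id = c("A", "B"),
                      protospacer_a = c("ACGTACGTAC", "ACGTACGTAG"))
    fq <- writeFastq("ACGTACGTA", tempfile(fileext = ".fastq"))
    expect_error(countProtospacers(fq, lib, offset = 0, length = 9),
                 "collisions")
})

test_that("downsampling equalizes totals and is a no-op at equal depth", {
    m <- matrix(c(10L, 20L, 30L, 25L, 20L, 15L), 3,
                dimnames = list(c("a", "b", "c"), c("s1", "s2")))
    expect_identical(downsampleToCommonDepth(m, seed = 1), m)
    m2 <- cbind(m, s3 = c(50L, 60L, 70L))
    out <- downsampleToCommonDepth(m2, seed = 1)
    expect_true(all(colSums(out) == min(colSums(m2))))
    expect_true(all(out <= m2))
    expect_error(downsampleToCommonDepth(cbind(m, s0 = c(0L, 0L, 0L))),
                 "s0")
})

test_that("downsampling matches hypergeometric moments", {
    m <- matrix(c(800L, 200L, 400L, 100L), 2,
                dimnames = list(c("a", "b"), c("big", "small")))
    draws <- vapply(seq_len(10000), function(b)
        downsampleToCommonDepth(m, seed = b)[1, "big"], 0L)
    # X ~ Hypergeometric(N = 1000, K = 800, n = 500): mean 400,
    # var = n*K/N*(1-K/N)*(N-n)/(N-1)
    v <- 500 * 0.8 * 0.2 * (500 / 999)
    expect_lt(abs(mean(draws) - 400), 3 * sqrt(v / 10000))
})

test_that("mean-count filter applies the >= 50 threshold to all samples", {
    m <- rbind(keep50 = rep(50L, 4), drop49 = rep(49L, 4))
    colnames(m) <- paste0("s", 1:4)
    out <- filterLowAbundance(m, min_mean = 50)
    expect_identical(rownames(out), "keep50")
    expect_identical(attr(out, "excluded"), "drop49")

    m2 <- matrix(rep(c(10, 49.9, 50, 120, 0), each = 4), 5, 4, byrow = TRUE,
                 dimnames = list(paste0("c", 1:5), paste0("s", 1:4)))
    expect_identical(rownames(filterLowAbundance(m2, 50)), c("c3", "c4"))
    expect_identical(filterLowAbundance(m2, 0)[, ], m2[, ])
})
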
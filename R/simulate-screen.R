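#' Configuration for the synthetic CRISPRi screen generator
#'
#' Describes a dual-sgRNA screen with a shared post-transduction baseline (T0)
#' and replicated vehicle and drug arms sampled after ten days of growth
#' (T10). Each gene carries one dual-guide construct; non-targeting control
#' (NTC) pairs have no planted effect. Per-class effects are expressed per
#' population doubling: \code{gamma} acts in both arms (growth), \code{rho}
#' acts in the drug arm only (drug interaction).
#'
#' @param n_genes number of targeted genes (one construct each). The default
#'   2000 is a desk-scale library; \code{fullScaleScreenConfig()} gives the
#'   genome-wide composition (23483 genes, 1137 NTC pairs).
#' @param n_ntc_pairs number of non-targeting control constructs.
#' @param class_fractions named fractions over
#'   \code{essential}, \code{fitness_suppressor}, \code{resistance},
#'   \code{sensitizer}, \code{neutral}; must sum to 1.
#' @param gamma_effects per-class growth phenotype, log2 fold change per
#'   population doubling, applied in both arms.
#' @param rho_effects per-class drug-arm-only phenotype per doubling.
#' @param doublings named vector of population doublings per arm
#'   (\code{vehicle}, \code{drug}).
#' @param n_replicates T10 replicates per arm (T0 is a single shared sample).
#' @param depth_per_construct mean sequencing depth per construct; each sample
#'   column totals exactly \code{n_constructs * depth_per_construct} reads.
#' @param overdispersion Dirichlet-multinomial concentration scale; counts for
#'   a construct behave like negative binomial with dispersion about
#'   \code{1/overdispersion} on top of the multinomial sampling.
#' @param abundance_sigma log-normal spread (sdlog) of baseline construct
#'   abundances.
#' @param seed integer random seed.
#' @return A \code{ScreenSimConfig} object.
#' @seealso \code{\link{simulateScreen}}
#' @export
ScreenSimConfig <- function(n_genes = 2000L, n_ntc_pairs = 100L,
                            class_fractions = c(essential = 0.10,
                                                fitness_suppressor = 0.02,
                                                resistance = 0.01,
                                                sensitizer = 0.01,
                                                neutral = 0.86),
                            gamma_effects = c(essential = -0.3,
                                              fitness_suppressor = 0.2,
                                              resistance = 0,
                                              sensitizer = 0,
                                              neutral = 0),
                            rho_effects = c(essential = 0,
                                            fitness_suppressor = 0,
                                            resistance = 0.5,
                                            sensitizer = -0.5,
                                            neutral = 0),
                            doublings = c(vehicle = 8, drug = 6),
                            n_replicates = 3L,
                            depth_per_construct = 500,
                            overdispersion = 1000,
                            abundance_sigma = 0.5,
                            seed = 1L) {
    new("ScreenSimConfig",
        n_genes = as.integer(n_genes), n_ntc_pairs = as.integer(n_ntc_pairs),
        class_fractions = class_fractions, gamma_effects = gamma_effects,
        rho_effects = rho_effects, doublings = doublings,
        n_replicates = as.integer(n_replicates),
        depth_per_construct = depth_per_construct,
        overdispersion = overdispersion, abundance_sigma = abundance_sigma,
        seed = as.integer(seed))
}

#' @rdname ScreenSimConfig
#' @aliases ScreenSimConfig-class
#' @exportClass ScreenSimConfig
setClass("ScreenSimConfig",
    representation(n_genes = "integer", n_ntc_pairs = "integer",
                   class_fractions = "numeric", gamma_effects = "numeric",
                   rho_effects = "numeric", doublings = "numeric",
                   n_replicates = "integer", depth_per_construct = "numeric",
                   overdispersion = "numeric", abundance_sigma = "numeric",
                   seed = "integer"))

.SCREEN_CLASSES <- c("essential", "fitness_suppressor", "resistance",
                     "sensitizer", "neutral")

setValidity("ScreenSimConfig", function(object) {
    msg <- character()
    if (object@n_genes < 1L) msg <- c(msg, "n_genes must be positive")
    if (object@n_ntc_pairs < 1L) msg <- c(msg, "n_ntc_pairs must be positive")
    if (!setequal(names(object@class_fractions), .SCREEN_CLASSES))
        msg <- c(msg, paste0("class_fractions must be named over: ",
                             paste(.SCREEN_CLASSES, collapse = ", ")))
    else if (abs(sum(object@class_fractions) - 1) > 1e-9)
        msg <- c(msg, sprintf(
            "class_fractions must sum to 1 (got %.12g)",
            sum(object@class_fractions)))
    for (fld in c("gamma_effects", "rho_effects")) {
        v <- slot(object, fld)
        if (!setequal(names(v), .SCREEN_CLASSES))
            msg <- c(msg, paste0(fld, " must be named over the five classes"))
    }
    if (!setequal(names(object@doublings), c("vehicle", "drug")))
        msg <- c(msg, "doublings must be named over vehicle and drug")
    else if (any(object@doublings <= 0))
        msg <- c(msg, "doublings must be > 0")
    if (object@depth_per_construct <= 0)
        msg <- c(msg, "depth_per_construct must be > 0")
    if (object@overdispersion <= 0)
        msg <- c(msg, "overdispersion must be > 0")
    if (object@abundance_sigma < 0)
        msg <- c(msg, "abundance_sigma must be >= 0")
    if (object@n_replicates < 1L)
        msg <- c(msg, "n_replicates must be >= 1")
    if (length(msg)) msg else TRUE
})

#' Genome-wide screen composition preset
#'
#' The same generator at the composition of the genome-wide dual-sgRNA
#' library: 23483 targeted genes plus 1137 non-targeting control pairs.
#' Intended for scale checks only; the desk-scale default runs in seconds.
#'
#' @param ... overrides passed to \code{\link{ScreenSimConfig}}.
#' @return A \code{ScreenSimConfig}.
#' @export
fullScaleScreenConfig <- function(...) {
    ScreenSimConfig(n_genes = 23483L, n_ntc_pairs = 1137L, ...)
}

# Integer class counts by largest remainder so counts sum to n_genes exactly.
.classCounts <- function(fractions, n) {
    raw <- fractions[.SCREEN_CLASSES] * n
    base <- floor(raw)
    rem <- n - sum(base)
    if (rem > 0) {
        ord <- order(raw - base, decreasing = TRUE)
        base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
    }
    stats::setNames(as.integer(base), .SCREEN_CLASSES)
}

.randomProtospacers <- function(n, len = 20L) {
    repeat {
        ps <- vapply(seq_len(n), function(i)
            paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                  collapse = ""), "")
        if (!anyDuplicated(ps)) return(ps)
    }
}

#' Simulate a dual-condition pooled CRISPRi screen
#'
#' Generates a seeded screen with planted truth. Baseline construct
#' abundances are log-normal; the expected abundance of construct i at T10 is
#' proportional to \code{a_i * 2^(D * (gamma_i + rho_i * [drug arm]))} with D
#' the arm's population doublings. Counts for each sample are drawn
#' Dirichlet-multinomial: a relative-abundance vector is drawn from a
#' Dirichlet with concentration \code{overdispersion} times the expected
#' abundance scaled to mean 1, then counts are multinomial at total depth
#' \code{n_constructs * depth_per_construct}, so every sample column sums to
#' that total exactly.
#'
#' @param config a \code{\link{ScreenSimConfig}}.
#' @return A list with elements \code{experiment}
#'   (\linkS4class{ScreenExperiment}) and \code{truth} (data.frame with
#'   \code{construct_id}, \code{gene}, \code{class}; NTC constructs have
#'   class \code{"ntc"}).
#' @examples
#' sim <- simulateScreen(ScreenSimConfig(n_genes = 50, n_ntc_pairs = 10,
#'                                       seed = 1))
#' colSums(SummarizedExperiment::assay(sim$experiment))
#' table(sim$truth$class)
#' @export
simulateScreen <- function(config = ScreenSimConfig()) {
    stopifnot(is(config, "ScreenSimConfig"))
    validObject(config)
    set.seed(.substreamSeed(config@seed, "screen-sim"))

    counts_by_class <- .classCounts(config@class_fractions, config@n_genes)
    classes <- sample(rep(.SCREEN_CLASSES, counts_by_class))
    genes <- sprintf("GENE%05d", seq_len(config@n_genes))
    n_ntc <- config@n_ntc_pairs
    construct_id <- c(genes, sprintf("NTC%04d", seq_len(n_ntc)))
    gene <- c(genes, rep("NTC", n_ntc))
    cls <- c(classes, rep("ntc", n_ntc))
    n_con <- length(construct_id)

    gamma <- c(config@gamma_effects[classes], rep(0, n_ntc))
    rho <- c(config@rho_effects[classes], rep(0, n_ntc))

    a0 <- stats::rlnorm(n_con, meanlog = 0, sdlog = config@abundance_sigma)
    total_depth <- round(n_con * config@depth_per_construct)

    sheet <- data.frame(
        sample_id = c("T0",
                      paste0("vehicle_T10_", seq_len(config@n_replicates)),
                      paste0("drug_T10_", seq_len(config@n_replicates))),
        arm = c("baseline", rep("vehicle", config@n_replicates),
                rep("drug", config@n_replicates)),
        timepoint = c("T0", rep("T10", 2 * config@n_replicates)),
        replicate = c(1L, seq_len(config@n_replicates),
                      seq_len(config@n_replicates)),
        stringsAsFactors = FALSE)

    drawColumn <- function(expected) {
        w <- expected / mean(expected)
        alpha <- config@overdispersion * w
        p <- stats::rgamma(n_con, shape = alpha, rate = 1)
        p <- p / sum(p)
        as.integer(stats::rmultinom(1, size = total_depth, prob = p))
    }

    cts <- matrix(0L, n_con, nrow(sheet),
                  dimnames = list(construct_id, sheet$sample_id))
    for (j in seq_len(nrow(sheet))) {
        expected <- if (sheet$timepoint[j] == "T0") a0 else {
            D <- config@doublings[[sheet$arm[j]]]
            a0 * 2^(D * (gamma + rho * (sheet$arm[j] == "drug")))
        }
        cts[, j] <- drawColumn(expected)
    }

    lib <- data.frame(construct_id = construct_id, gene = gene,
                      protospacer_a = .randomProtospacers(n_con),
                      protospacer_b = .randomProtospacers(n_con),
                      is_ntc = gene == "NTC", stringsAsFactors = FALSE)
    se <- ScreenExperiment(cts, lib, sheet)
    metadata(se)$sim_config <- config
    metadata(se)$doublings <- config@doublings
    truth <- data.frame(construct_id = construct_id, gene = gene,
                        class = cls, stringsAsFactors = FALSE)
    list(experiment = se, truth = truth)
}
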
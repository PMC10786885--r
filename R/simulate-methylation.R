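#' Configuration for the synthetic methylation cohort generator
#'
#' Describes a beta-value matrix with planted sample groups. Each group owns a
#' set of informative probes whose mean beta differs from the rest of the
#' cohort by \code{beta_shift}; the remaining probes draw their means from a
#' bimodal two-component Beta mixture, emulating the characteristic bimodality
#' of array beta values. Per-sample noise is applied on the logit scale.
#' Probe-level artifacts targeted by the filtering rules (sex-chromosome
#' probes, SNP-overlapping probes, multi-mapping probes, detection failures)
#' are planted as mutually disjoint sets that never intersect the informative
#' probes.
#'
#' @param group_sizes integer vector of planted group sizes. The default
#'   25/8/86 mirrors a three-group tumor cohort of 119 samples.
#' @param n_probes total number of probes.
#' @param n_informative_per_group informative probes per group.
#' @param beta_shift mean beta separation of informative probes between the
#'   owning group and the rest (on the beta scale, before noise).
#' @param background_shape1,background_shape2 shape pairs of the two Beta
#'   mixture components for uninformative probe means.
#' @param background_mix mixing weight of the first component.
#' @param sample_noise_sd per-entry noise standard deviation on the logit
#'   scale.
#' @param n_flagged named counts of planted flagged probes:
#'   \code{sex_chrom}, \code{snp_overlap}, \code{multimap},
#'   \code{detection_fail}.
#' @param seed integer random seed.
#' @return A \code{MethSimConfig} object.
#' @seealso \code{\link{simulateMethylation}}
#' @export
MethSimConfig <- function(group_sizes = c(25L, 8L, 86L),
                          n_probes = 20000L,
                          n_informative_per_group = 500L,
                          beta_shift = 0.4,
                          background_shape1 = c(2, 10),
                          background_shape2 = c(10, 2),
                          background_mix = 0.5,
                          sample_noise_sd = 0.05,
                          n_flagged = c(sex_chrom = 1000L, snp_overlap = 500L,
                                        multimap = 500L, detection_fail = 200L),
                          seed = 1L) {
    new("MethSimConfig", group_sizes = as.integer(group_sizes),
        n_probes = as.integer(n_probes),
        n_informative_per_group = as.integer(n_informative_per_group),
        beta_shift = beta_shift, background_shape1 = background_shape1,
        background_shape2 = background_shape2,
        background_mix = background_mix,
        sample_noise_sd = sample_noise_sd,
        n_flagged = vapply(n_flagged, as.integer, 0L),
        seed = as.integer(seed))
}

#' @rdname MethSimConfig
#' @aliases MethSimConfig-class
#' @exportClass MethSimConfig
setClass("MethSimConfig",
    representation(group_sizes = "integer", n_probes = "integer",
                   n_informative_per_group = "integer", beta_shift = "numeric",
                   background_shape1 = "numeric", background_shape2 = "numeric",
                   background_mix = "numeric", sample_noise_sd = "numeric",
                   n_flagged = "integer", seed = "integer"))

.FLAG_KINDS <- c("sex_chrom", "snp_overlap", "multimap", "detection_fail")

setValidity("MethSimConfig", function(object) {
    msg <- character()
    if (length(object@group_sizes) == 0L)
        msg <- c(msg, "group_sizes must not be empty")
    else if (any(object@group_sizes < 1L))
        msg <- c(msg, "group_sizes must be positive")
    if (object@beta_shift <= 0 || object@beta_shift > 0.9)
        msg <- c(msg, "beta_shift must be in (0, 0.9]")
    if (any(c(object@background_shape1, object@background_shape2) <= 0))
        msg <- c(msg, "Beta mixture shapes must be > 0")
    if (object@background_mix < 0 || object@background_mix > 1)
        msg <- c(msg, "background_mix must be in [0, 1]")
    if (object@sample_noise_sd < 0)
        msg <- c(msg, "sample_noise_sd must be >= 0")
    if (!setequal(names(object@n_flagged), .FLAG_KINDS))
        msg <- c(msg, paste0("n_flagged must be named over: ",
                             paste(.FLAG_KINDS, collapse = ", ")))
    n_g <- length(object@group_sizes)
    need <- n_g * object@n_informative_per_group + sum(object@n_flagged)
    if (need > object@n_probes)
        msg <- c(msg, sprintf(
            "n_probes (%d) too small for informative plus flagged probes (%d)",
            object@n_probes, need))
    if (length(msg)) msg else TRUE
})

#' Simulate a methylation cohort with planted groups
#'
#' Generates a seeded probes x samples beta matrix, detection p-values, probe
#' annotation and planted truth. Informative probes of group g have mean beta
#' differing by approximately \code{beta_shift} between group g and the other
#' samples before noise; per-entry noise is normal on the logit scale, so all
#' values stay inside (0, 1). Probes planted as detection failures carry a
#' detection p-value of at least 0.05 in at least one sample; all other
#' entries are well below the threshold.
#'
#' @param config a \code{\link{MethSimConfig}}.
#' @return A list with \code{experiment} (a
#'   \linkS4class{MethylationExperiment} with assays \code{beta} and
#'   \code{detp}) and \code{truth} (list with \code{samples}: sample_id,
#'   group; and \code{probes}: probe_id, informative_group (NA for
#'   uninformative), flag (NA or one of the filter rules)).
#' @examples
#' sim <- simulateMethylation(MethSimConfig(group_sizes = c(6, 6),
#'                                          n_probes = 500,
#'                                          n_informative_per_group = 50,
#'                                          n_flagged = c(sex_chrom = 20,
#'                                                        snp_overlap = 10,
#'                                                        multimap = 10,
#'                                                        detection_fail = 5),
#'                                          seed = 1))
#' dim(SummarizedExperiment::assay(sim$experiment, "beta"))
#' @export
simulateMethylation <- function(config = MethSimConfig()) {
    stopifnot(is(config, "MethSimConfig"))
    validObject(config)
    if (any(config@group_sizes < 2L))
        message("note: planted groups of size 1 are hard to recover")
    set.seed(.substreamSeed(config@seed, "meth-sim"))

    gs <- config@group_sizes
    n_s <- sum(gs)
    n_p <- config@n_probes
    n_g <- length(gs)
    n_inf <- config@n_informative_per_group
    group <- rep(seq_len(n_g), gs)
    sample_id <- sprintf("S%03d", seq_len(n_s))
    probe_id <- sprintf("cg%06d", seq_len(n_p))

    # allocate disjoint probe roles from one permutation
    perm <- sample.int(n_p)
    take <- function(n) {
        out <- perm[seq_len(n)]
        perm <<- perm[-seq_len(n)]
        out
    }
    inf_idx <- lapply(seq_len(n_g), function(g) take(n_inf))
    flag_idx <- lapply(config@n_flagged[.FLAG_KINDS], take)

    # probe means: bimodal background
    comp <- stats::runif(n_p) < config@background_mix
    m <- ifelse(comp,
                stats::rbeta(n_p, config@background_shape1[1],
                             config@background_shape1[2]),
                stats::rbeta(n_p, config@background_shape2[1],
                             config@background_shape2[2]))
    M <- matrix(rep(m, n_s), n_p, n_s,
                dimnames = list(probe_id, sample_id))

    # informative probes: shifted mean in the owning group
    shift <- config@beta_shift
    for (g in seq_len(n_g)) {
        idx <- inf_idx[[g]]
        up <- stats::runif(n_inf) < 0.5
        m_other <- ifelse(up, stats::runif(n_inf, 0.05, 0.95 - shift),
                          stats::runif(n_inf, 0.05 + shift, 0.95))
        m_group <- m_other + ifelse(up, shift, -shift)
        M[idx, ] <- m_other
        M[idx, group == g] <- m_group
    }

    eta <- stats::qlogis(.clamp(M, 1e-4, 1 - 1e-4))
    beta <- stats::plogis(eta + stats::rnorm(length(eta),
                                             sd = config@sample_noise_sd))
    dim(beta) <- dim(M)
    dimnames(beta) <- dimnames(M)

    detp <- matrix(stats::runif(n_p * n_s, 0, 0.01), n_p, n_s,
                   dimnames = dimnames(M))
    for (i in flag_idx$detection_fail) {
        n_bad <- sample.int(3L, 1L)
        detp[i, sample.int(n_s, n_bad)] <- stats::runif(n_bad, 0.05, 0.8)
    }

    chrom <- sample(paste0("chr", 1:22), n_p, replace = TRUE)
    chrom[flag_idx$sex_chrom] <- sample(c("chrX", "chrY"),
                                        length(flag_idx$sex_chrom),
                                        replace = TRUE)
    snp <- logical(n_p); snp[flag_idx$snp_overlap] <- TRUE
    mm <- logical(n_p); mm[flag_idx$multimap] <- TRUE
    ann <- data.frame(probe_id = probe_id, chrom = chrom,
                      snp_overlap = snp, multimap = mm,
                      stringsAsFactors = FALSE)

    se <- MethylationExperiment(beta, ann, detp = detp)
    metadata(se)$sim_config <- config

    informative_group <- rep(NA_integer_, n_p)
    for (g in seq_len(n_g)) informative_group[inf_idx[[g]]] <- g
    flag <- rep(NA_character_, n_p)
    for (kind in .FLAG_KINDS) flag[flag_idx[[kind]]] <- kind
    truth <- list(
        samples = data.frame(sample_id = sample_id, group = group,
                             stringsAsFactors = FALSE),
        probes = data.frame(probe_id = probe_id,
                            informative_group = informative_group,
                            flag = flag, stringsAsFactors = FALSE))
    list(experiment = se, truth = truth)
}
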
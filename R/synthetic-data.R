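#' @include AllClasses.R variant-sites.R pool-counts.R curation-filters.R
#'   vcf-io.R
NULL

# region layout used by the simulator: regions separated by fixed gaps on
# a single synthetic chromosome
SIM_GAP <- 200L

#' Simulate a reference sequence for the amplicon panel
#'
#' One synthetic chromosome holding \code{n_regions} amplicons of
#' \code{region_len} bp separated by fixed inter-region gaps.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return named \linkS4class{DNAStringSet} with one chromosome
#'   \code{"chr1"}.
#' @export
simulateReference <- function(cfg) {
    set.seed(cfg@seed)
    total <- cfg@n_regions * (cfg@region_len + SIM_GAP) + SIM_GAP
    seq <- paste(sample(DNA_BASES4, total, replace = TRUE), collapse = "")
    out <- DNAStringSet(seq)
    names(out) <- "chr1"
    out
}

#' Simulate the target-region panel
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @return A \linkS4class{TargetRegions} object matching the layout of
#'   \code{\link{simulateReference}}.
#' @export
simulateRegions <- function(cfg) {
    starts <- SIM_GAP + 1L +
        (seq_len(cfg@n_regions) - 1L) * (cfg@region_len + SIM_GAP)
    TargetRegions(sprintf("r%03d", seq_len(cfg@n_regions)), "chr1",
                  starts, starts + cfg@region_len - 1L,
                  primer_pair = sprintf("primer%03d",
                                        seq_len(cfg@n_regions)),
                  expected_amplicon_len = cfg@region_len)
}

#' Simulate pooled allele read counts with ground truth
#'
#' Plants \code{n_sites} biallelic SNPs inside the target regions. Each
#' site draws a population frequency from the rare/common mixture (or
#' uses \code{fixed_pool_fraction}); each pool then draws its carrier
#' allele copies binomially from \code{ploidy * samples_per_pool}
#' chromosomes, reads are drawn multinomially over the four nucleotides
#' at the pool allele fraction, and each read is independently corrupted
#' to a uniformly chosen other base with probability
#' \code{base_error_rate}. Everything is a deterministic function of the
#' config seed.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param reference,regions optional pre-built reference and regions
#'   (regenerated from \code{cfg} when omitted).
#' @return list with \code{counts} (\linkS4class{PoolCounts}),
#'   \code{truth} (list: \code{sites} data.frame with the true population
#'   frequency per site, \code{pool_fraction} and \code{alt_copies}
#'   matrices sites x pools), \code{sites}
#'   (\linkS4class{VariantSites}), \code{regions} and \code{reference}.
#' @export
simulatePools <- function(cfg, reference = NULL, regions = NULL) {
    if (is.null(reference)) reference <- simulateReference(cfg)
    if (is.null(regions)) regions <- simulateRegions(cfg)
    set.seed(cfg@seed)
    n <- cfg@n_sites; np <- cfg@n_pools
    chroms_ok <- width(regions) >= 1L
    region_pos <- unlist(lapply(which(chroms_ok), function(i)
        seq(start(regions)[i], end(regions)[i])))
    if (n > length(region_pos))
        stop("more sites requested than targeted positions")
    pos <- sort(sample(region_pos, n))
    refseq <- strsplit(as.character(reference[["chr1"]]), "")[[1L]]
    ref <- refseq[pos]
    alt <- vapply(ref, function(b) sample(setdiff(DNA_BASES4, b), 1L),
                  character(1), USE.NAMES = FALSE)
    nh <- cfg@ploidy * cfg@samples_per_pool
    if (length(cfg@fixed_pool_fraction)) {
        f <- rep(cfg@fixed_pool_fraction, n)
        frac <- matrix(cfg@fixed_pool_fraction, n, np)
        copies <- round(frac * nh)
    } else {
        rare <- stats::runif(n) < cfg@fraction_rare
        f <- ifelse(rare,
                    stats::runif(n, cfg@rare_freq_range[1L],
                                 cfg@rare_freq_range[2L]),
                    stats::runif(n, cfg@common_freq_range[1L],
                                 cfg@common_freq_range[2L]))
        copies <- matrix(stats::rbinom(n * np, nh, rep(f, np)), n, np)
        frac <- copies / nh
    }
    depth <- rep_len(cfg@depth_per_pool, np)
    e <- cfg@base_error_rate
    pool_ids <- sprintf("pool%d", seq_len(np))
    zero <- matrix(0L, n, np, dimnames = list(NULL, pool_ids))
    nuc <- list(A = zero, C = zero, G = zero, T = zero)
    others <- lapply(seq_len(n), function(i)
        setdiff(DNA_BASES4, c(ref[i], alt[i])))
    for (j in seq_len(np)) {
        p <- frac[, j]
        p_alt <- p * (1 - e) + (1 - p) * e / 3
        p_ref <- (1 - p) * (1 - e) + p * e / 3
        p_err <- e / 3
        for (i in seq_len(n)) {
            probs <- c(p_ref[i], p_alt[i], p_err, p_err)
            draw <- stats::rmultinom(1L, depth[j], probs)[, 1L]
            nuc[[ref[i]]][i, j] <- draw[1L]
            nuc[[alt[i]]][i, j] <- draw[2L]
            nuc[[others[[i]][1L]]][i, j] <- draw[3L]
            nuc[[others[[i]][2L]]][i, j] <- draw[4L]
        }
    }
    sites <- VariantSites(rep("chr1", n), pos, ref, alt)
    counts <- poolCounts(sites, pool_ids, nuc$A, nuc$C, nuc$G, nuc$T,
                         n_samples = cfg@samples_per_pool,
                         ploidy = cfg@ploidy)
    truth <- list(
        sites = data.frame(site = seq_len(n), chrom = "chr1", pos = pos,
                           ref = ref, alt = alt, true_freq = f,
                           stringsAsFactors = FALSE),
        pool_fraction = matrix(frac, n, np,
                               dimnames = list(NULL, pool_ids)),
        alt_copies = matrix(copies, n, np,
                            dimnames = list(NULL, pool_ids)))
    list(counts = counts, truth = truth, sites = sites,
         regions = regions, reference = reference)
}

#' Simulate an aligned-fragment table with planted capture rate
#'
#' Emits, per pool, \code{n_fragments} fragments of which a planted
#' fraction are assignable on-target fragments (full amplicon span with a
#' small jitter that preserves 90\% reciprocal overlap). The rest split
#' evenly between improper pairs, multi-mappers and off-target placements
#' that fail reciprocal overlap.
#'
#' @param cfg a \linkS4class{SimConfig}.
#' @param regions target regions (regenerated from \code{cfg} when
#'   omitted).
#' @param on_target_fraction planted capture rate (default 0.91).
#' @param n_fragments fragments per pool (default 10000).
#' @return fragments as returned by \code{\link{alignedFragments}}.
#' @export
simulateFragments <- function(cfg, regions = NULL,
                              on_target_fraction = 0.91,
                              n_fragments = 10000L) {
    if (is.null(regions)) regions <- simulateRegions(cfg)
    set.seed(cfg@seed)
    np <- cfg@n_pools
    total <- np * n_fragments
    ridx <- sample(length(regions), total, replace = TRUE)
    rs <- start(regions)[ridx]; re <- end(regions)[ridx]
    rlen <- re - rs + 1L
    on <- stats::runif(total) < on_target_fraction
    max_jit <- pmax(0L, as.integer(floor(rlen * 0.04)))
    jit <- as.integer(round(stats::runif(total, -max_jit, max_jit)))
    start <- rs + jit; end <- re + jit
    proper <- rep(TRUE, total); uniq <- rep(TRUE, total)
    off_kind <- sample(3L, total, replace = TRUE)
    bad <- !on
    # flavour 1: improper pair; 2: multimapper; 3: off-target placement
    proper[bad & off_kind == 1L] <- FALSE
    uniq[bad & off_kind == 2L] <- FALSE
    shift <- which(bad & off_kind == 3L)
    start[shift] <- pmax(1L, rs[shift] - as.integer(rlen[shift] %/% 2L))
    end[shift] <- start[shift] + rlen[shift] - 1L
    alignedFragments("chr1", start, end,
                     rep(sprintf("pool%d", seq_len(np)),
                         each = n_fragments),
                     proper, uniq, max_frag_len = max(rlen) + 1L)
}

#' Simulate multi-caller VCF callsets from planted truth
#'
#' Each simulated pipeline calls a planted site if and only if its
#' overall alternative-allele fraction (depth-weighted over pools)
#' reaches the pipeline's detection floor, plus Poisson false-positive
#' calls at untargeted positions at the profile's rate (expected false
#' positives per true site). One VCF per pipeline is written.
#'
#' @param sim result of \code{\link{simulatePools}}.
#' @param cfg the \linkS4class{SimConfig} used to generate \code{sim}.
#' @param dir output directory for the VCFs.
#' @return list with \code{files} (named vector of VCF paths),
#'   \code{called} (logical matrix sites x pipelines of true-site calls)
#'   and \code{false_positives} (per pipeline, data.frame of FP atoms).
#' @export
simulateCallsets <- function(sim, cfg, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    set.seed(cfg@seed)
    prof <- cfg@caller_profiles
    truth <- sim$truth
    overall <- rowMeans(truth$pool_fraction)
    n <- nrow(truth$sites)
    called <- matrix(FALSE, n, nrow(prof),
                     dimnames = list(NULL, prof$pipeline_id))
    files <- character(nrow(prof))
    fps <- vector("list", nrow(prof))
    refseq <- strsplit(as.character(sim$reference[["chr1"]]), "")[[1L]]
    region_pos <- unlist(lapply(seq_along(sim$regions), function(i)
        seq(start(sim$regions)[i], end(sim$regions)[i])))
    free_pos <- setdiff(region_pos, truth$sites$pos)
    for (k in seq_len(nrow(prof))) {
        hit <- overall >= prof$maf_detection_floor[k] & overall > 0
        called[, k] <- hit
        n_fp <- stats::rpois(1L, prof$false_positive_rate[k] * n)
        n_fp <- min(n_fp, length(free_pos))
        fp_pos <- sort(sample(free_pos, n_fp))
        fp_ref <- refseq[fp_pos]
        fp_alt <- vapply(fp_ref, function(b)
            sample(setdiff(DNA_BASES4, b), 1L), character(1),
            USE.NAMES = FALSE)
        fps[[k]] <- data.frame(chrom = rep("chr1", n_fp), pos = fp_pos,
                               ref = fp_ref, alt = fp_alt,
                               stringsAsFactors = FALSE)
        chrom <- c(truth$sites$chrom[hit], fps[[k]]$chrom)
        pos <- c(truth$sites$pos[hit], fps[[k]]$pos)
        ref <- c(truth$sites$ref[hit], fps[[k]]$ref)
        alt <- c(truth$sites$alt[hit], fps[[k]]$alt)
        o <- order(pos)
        vs <- VariantSites(chrom[o], pos[o], ref[o], alt[o],
                           provenance = rep(list(prof$pipeline_id[k]),
                                            length(o)))
        files[k] <- file.path(dir, paste0(prof$pipeline_id[k], ".vcf"))
        writeSitesVcf(vs, files[k])
    }
    names(files) <- prof$pipeline_id
    names(fps) <- prof$pipeline_id
    list(files = files, called = called, false_positives = fps)
}

#' Detection power of the curation cascade
#'
#' Monte-Carlo estimate of the probability that a planted biallelic SNP
#' at a given within-pool allele fraction survives the full filter
#' cascade. Each replicate simulates read counts for all pools at the
#' fixed fraction (isolating read-sampling and base-error noise from
#' carrier-sampling noise) and runs \code{\link{applyCascade}} on the
#' single-site callset.
#'
#' @param depth per-pool read depth at the site.
#' @param true_freq within-pool alternative-allele fraction.
#' @param error_rate base-call error rate.
#' @param filter_cfg a \linkS4class{FilterConfig}.
#' @param n_reps Monte-Carlo replicates (at least 100).
#' @param seed integer seed.
#' @param n_pools pools in the design (default 8).
#' @return list with \code{power}, \code{se} (binomial standard error)
#'   and \code{n_reps}.
#' @export
detectionPower <- function(depth, true_freq, error_rate,
                           filter_cfg = filterConfig(), n_reps = 200L,
                           seed = 1L, n_pools = 8L) {
    stopifnot(n_reps >= 100L)
    cfg <- simConfig(n_pools = n_pools, n_sites = n_reps,
                     n_regions = max(2L, ceiling(n_reps / 500L)),
                     region_len = 600L,
                     fixed_pool_fraction = true_freq,
                     depth_per_pool = depth,
                     base_error_rate = error_rate, seed = seed)
    sim <- simulatePools(cfg)
    res <- applyCascade(sim$sites, sim$counts, filter_cfg)
    p <- mean(res$kept)
    list(power = p, se = sqrt(p * (1 - p) / n_reps), n_reps = n_reps)
}
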
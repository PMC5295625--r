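#' @import methods
#' @importFrom S4Vectors DataFrame mcols mcols<- metadata metadata<-
#' @importFrom IRanges IRanges CharacterList
#' @importFrom GenomicRanges GRanges seqnames start end width findOverlaps
#'   pintersect granges
NULL

DNA_BASES4 <- c("A", "C", "G", "T")

#' Primer-defined target regions of an amplicon panel
#'
#' A \code{TargetRegions} object is a \linkS4class{GRanges} holding one range
#' per amplicon (1-based, inclusive coordinates) with three required metadata
#' columns: \code{region_id} (unique identifier), \code{primer_pair} (label of
#' the primer pair that amplifies the region) and
#' \code{expected_amplicon_len} (expected amplicon length in bp).
#'
#' @export
setClass("TargetRegions", contains = "GRanges")

setValidity("TargetRegions", function(object) {
    msg <- NULL
    need <- c("region_id", "primer_pair", "expected_amplicon_len")
    miss <- setdiff(need, colnames(mcols(object)))
    if (length(miss))
        msg <- c(msg, paste("missing metadata column(s):",
                            paste(miss, collapse = ", ")))
    else {
        if (anyDuplicated(mcols(object)$region_id))
            msg <- c(msg, "region_id values must be unique")
        if (any(mcols(object)$expected_amplicon_len <= 0))
            msg <- c(msg, "expected_amplicon_len must be positive")
    }
    if (length(object) && any(width(object) <= 0))
        msg <- c(msg, "regions must have positive width")
    if (is.null(msg)) TRUE else msg
})

#' Construct a TargetRegions object
#'
#' @param region_id character vector of unique region identifiers.
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @param primer_pair character vector naming the primer pair per region;
#'   defaults to \code{region_id}.
#' @param expected_amplicon_len integer vector of expected amplicon lengths
#'   in bp; defaults to the region width.
#' @return A \linkS4class{TargetRegions} object.
#' @examples
#' tr <- TargetRegions("r1", "chr1", 101, 700)
#' width(tr)
#' @export
TargetRegions <- function(region_id, chrom, start, end,
                          primer_pair = region_id,
                          expected_amplicon_len = end - start + 1L) {
    if (any(end < start))
        stop("malformed interval: end < start")
    gr <- GRanges(chrom, IRanges(as.integer(start), as.integer(end)))
    mcols(gr) <- DataFrame(region_id = as.character(region_id),
                           primer_pair = as.character(primer_pair),
                           expected_amplicon_len =
                               as.integer(expected_amplicon_len))
    new("TargetRegions", gr)
}

#' Normalized variant sites with per-pipeline provenance
#'
#' A \code{VariantSites} object stores a set of normalized variant sites.
#' Each site is identified by \code{(chrom, pos, ref)} and carries one or
#' more alternative alleles; sites with a single alternative allele are
#' classified as biallelic SNPs or biallelic indels according to allele
#' lengths, sites with several alternative alleles as multiallelic. The
#' \code{provenance} slot records, per site, the identifiers of the
#' discovery pipelines (aligner/caller combinations) that reported it.
#'
#' @slot chrom character, chromosome per site.
#' @slot pos integer, 1-based position per site.
#' @slot ref character, reference allele per site.
#' @slot alt \linkS4class{CharacterList}, alternative alleles per site.
#' @slot provenance \linkS4class{CharacterList}, pipeline ids per site.
#' @export
setClass("VariantSites",
    representation(chrom = "character", pos = "integer", ref = "character",
                   alt = "CharacterList", provenance = "CharacterList"))

setValidity("VariantSites", function(object) {
    n <- length(object@chrom)
    msg <- NULL
    if (length(object@pos) != n || length(object@ref) != n ||
        length(object@alt) != n || length(object@provenance) != n)
        msg <- c(msg, "all slots must have equal length")
    else if (n) {
        if (any(lengths(object@alt) < 1L))
            msg <- c(msg, "every site needs at least one alternative allele")
        if (any(unlist(object@alt) == rep(object@ref, lengths(object@alt))))
            msg <- c(msg, "ref allele must differ from every alt allele")
        bad <- grepl("[^ACGT]", c(object@ref, unlist(object@alt)))
        if (any(bad))
            msg <- c(msg, "alleles must be uppercase strings over A,C,G,T")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a VariantSites object
#'
#' @param chrom character vector of chromosome names.
#' @param pos integer vector of 1-based positions.
#' @param ref character vector of reference alleles.
#' @param alt character vector of single alternative alleles, or a list /
#'   \code{CharacterList} of alternative alleles per site.
#' @param provenance optional list of pipeline-id character vectors per site.
#' @return A \linkS4class{VariantSites} object.
#' @examples
#' vs <- VariantSites("chr1", c(100L, 200L), c("A", "G"), c("G", "T"))
#' vtype(vs)
#' @export
VariantSites <- function(chrom, pos, ref, alt, provenance = NULL) {
    n <- max(length(chrom), length(pos), length(ref))
    chrom <- rep_len(as.character(chrom), n)
    pos <- rep_len(as.integer(pos), n)
    ref <- rep_len(toupper(as.character(ref)), n)
    if (!is(alt, "CharacterList")) {
        if (!is.list(alt)) alt <- as.list(as.character(alt))
        alt <- CharacterList(lapply(alt, function(a) toupper(as.character(a))))
    }
    if (length(alt) != n) alt <- rep(alt, length.out = n)
    if (is.null(provenance))
        provenance <- CharacterList(rep(list(character(0)), n))
    else if (!is(provenance, "CharacterList"))
        provenance <- CharacterList(provenance)
    if (length(provenance) != n)
        provenance <- rep(provenance, length.out = n)
    new("VariantSites", chrom = chrom, pos = pos, ref = ref,
        alt = alt, provenance = provenance)
}

#' Per-pool per-allele read counts at variant sites
#'
#' A \code{PoolCounts} object is a
#' \linkS4class{RangedSummarizedExperiment} with one row per variant site
#' and one column per DNA pool. SNP sites carry four assays \code{A},
#' \code{C}, \code{G}, \code{T} with the read count observed for each
#' nucleotide; indel sites carry counts in the \code{refCount} and
#' \code{altCount} assays (reads exactly matching the reference or the
#' alternative allele span) and \code{NA} in the nucleotide assays.
#' \code{rowData} holds \code{ref}, \code{alt} and \code{vtype};
#' \code{colData} holds the pool design (\code{pool_id}, \code{n_samples},
#' \code{ploidy}).
#'
#' @export
setClass("PoolCounts", contains = "RangedSummarizedExperiment")

setValidity("PoolCounts", function(object) {
    msg <- NULL
    need <- c("A", "C", "G", "T", "refCount", "altCount")
    miss <- setdiff(need, SummarizedExperiment::assayNames(object))
    if (length(miss))
        msg <- c(msg, paste("missing assay(s):", paste(miss, collapse = ", ")))
    needrd <- c("ref", "alt", "vtype")
    if (!all(needrd %in% colnames(SummarizedExperiment::rowData(object))))
        msg <- c(msg, "rowData needs columns ref, alt, vtype")
    if (!all(c("pool_id", "n_samples", "ploidy") %in%
             colnames(SummarizedExperiment::colData(object))))
        msg <- c(msg, "colData needs columns pool_id, n_samples, ploidy")
    for (a in intersect(need, SummarizedExperiment::assayNames(object))) {
        v <- SummarizedExperiment::assay(object, a)
        if (any(v < 0, na.rm = TRUE))
            msg <- c(msg, paste("negative counts in assay", a))
    }
    if (is.null(msg)) TRUE else msg
})

#' Thresholds of the variant curation cascade
#'
#' Parameter object holding every tunable threshold of the filter cascade:
#' \describe{
#'   \item{min_total_depth}{minimum read depth at a site (default 10000);
#'     interpreted under \code{aggregate_mode}.}
#'   \item{min_pools_present}{minimum number of pools in which the variant
#'     must be present (default 2).}
#'   \item{min_alt_reads_presence}{minimum alternative-allele reads for a
#'     variant to count as present in a pool (default 1).}
#'   \item{error_ratio_threshold}{minimum ratio between the second-ranked
#'     allele count and the sequencing-error estimate (default 5).}
#'   \item{error_rank_lo, error_rank_hi}{ranks, in descending count order,
#'     of the allele counts averaged to estimate sequencing errors
#'     (defaults 3 and 4, i.e. the two smallest nucleotide counts).}
#'   \item{aggregate_mode}{\code{"summed_across_pools"} (default) applies
#'     the depth filter and the error statistic to counts summed over all
#'     pools; \code{"per_pool_any"} passes a site if any single pool
#'     passes.}
#' }
#'
#' @export
setClass("FilterConfig",
    representation(min_total_depth = "numeric",
                   min_pools_present = "integer",
                   min_alt_reads_presence = "integer",
                   error_ratio_threshold = "numeric",
                   error_rank_lo = "integer",
                   error_rank_hi = "integer",
                   aggregate_mode = "character"))

setValidity("FilterConfig", function(object) {
    msg <- NULL
    if (object@min_total_depth < 0 || object@min_alt_reads_presence < 0 ||
        object@error_ratio_threshold < 0)
        msg <- c(msg, "thresholds must be non-negative")
    if (object@min_pools_present < 1L)
        msg <- c(msg, "min_pools_present must be at least 1")
    if (object@error_rank_lo < 1L || object@error_rank_hi > 4L ||
        object@error_rank_lo > object@error_rank_hi)
        msg <- c(msg, "error ranks must satisfy 1 <= lo <= hi <= 4")
    if (!object@aggregate_mode %in% c("summed_across_pools", "per_pool_any"))
        msg <- c(msg, "aggregate_mode must be 'summed_across_pools' or 'per_pool_any'")
    if (is.null(msg)) TRUE else msg
})

#' @rdname FilterConfig-class
#' @param min_total_depth,min_pools_present,min_alt_reads_presence,error_ratio_threshold,error_rank_lo,error_rank_hi,aggregate_mode
#'   see the class description.
#' @return A \code{FilterConfig} object.
#' @examples
#' filterConfig(error_ratio_threshold = 10)
#' @export
filterConfig <- function(min_total_depth = 10000,
                         min_pools_present = 2L,
                         min_alt_reads_presence = 1L,
                         error_ratio_threshold = 5,
                         error_rank_lo = 3L,
                         error_rank_hi = 4L,
                         aggregate_mode = c("summed_across_pools",
                                            "per_pool_any")) {
    new("FilterConfig",
        min_total_depth = as.numeric(min_total_depth),
        min_pools_present = as.integer(min_pools_present),
        min_alt_reads_presence = as.integer(min_alt_reads_presence),
        error_ratio_threshold = as.numeric(error_ratio_threshold),
        error_rank_lo = as.integer(error_rank_lo),
        error_rank_hi = as.integer(error_rank_hi),
        aggregate_mode = match.arg(aggregate_mode))
}

#' Configuration of the pooled-sequencing simulator
#'
#' Describes the experiment the simulator emulates: 8 pools of about 200
#' diploid samples each, amplicons of 600 bp, per-pool per-site read depths
#' of order 10^4, a site-frequency spectrum dominated by rare alleles, and
#' uniform base-call errors. See \code{\link{simConfig}} for defaults.
#'
#' @export
setClass("SimConfig",
    representation(n_pools = "integer", samples_per_pool = "integer",
                   ploidy = "integer", n_regions = "integer",
                   region_len = "integer", n_sites = "integer",
                   fraction_rare = "numeric", rare_freq_range = "numeric",
                   common_freq_range = "numeric",
                   fixed_pool_fraction = "numeric",
                   depth_per_pool = "integer", base_error_rate = "numeric",
                   caller_profiles = "data.frame", seed = "integer"))

setValidity("SimConfig", function(object) {
    msg <- NULL
    if (object@base_error_rate < 0 || object@base_error_rate > 1)
        msg <- c(msg, "base_error_rate must be in [0,1]")
    if (object@fraction_rare < 0 || object@fraction_rare > 1)
        msg <- c(msg, "fraction_rare must be in [0,1]")
    if (any(object@depth_per_pool < 0))
        msg <- c(msg, "depths must be non-negative")
    if (length(object@seed) != 1L || is.na(object@seed))
        msg <- c(msg, "a single integer seed is mandatory")
    if (length(object@fixed_pool_fraction) &&
        (object@fixed_pool_fraction < 0 || object@fixed_pool_fraction > 1))
        msg <- c(msg, "fixed_pool_fraction must be in [0,1]")
    if (nrow(object@caller_profiles) &&
        !all(c("pipeline_id", "maf_detection_floor", "false_positive_rate")
             %in% colnames(object@caller_profiles)))
        msg <- c(msg, paste("caller_profiles needs columns pipeline_id,",
                            "maf_detection_floor, false_positive_rate"))
    if (is.null(msg)) TRUE else msg
})

#' @rdname SimConfig-class
#' @param n_pools number of DNA pools (default 8).
#' @param samples_per_pool diploid samples per pool (default 200).
#' @param ploidy sample ploidy (default 2).
#' @param n_regions number of amplicon target regions (default 100).
#' @param region_len amplicon length in bp (default 600).
#' @param n_sites number of variant sites to plant (default 1000).
#' @param fraction_rare fraction of sites with a rare population frequency
#'   (default 0.65).
#' @param rare_freq_range range of rare population frequencies; defaults to
#'   \code{c(1/(ploidy * samples_per_pool), 0.01)}, i.e. from the
#'   single-carrier floor up to 1\%.
#' @param common_freq_range range of common frequencies (default
#'   \code{c(0.01, 0.5)}).
#' @param fixed_pool_fraction when set, every pool carries exactly this
#'   alternative-allele fraction instead of drawing carriers binomially;
#'   used for calibration experiments.
#' @param depth_per_pool per-site per-pool read depth (default 20000);
#'   recycled over pools.
#' @param base_error_rate probability that a read reports a uniformly
#'   chosen other base at the site (default 0.002).
#' @param caller_profiles data.frame with columns \code{pipeline_id},
#'   \code{maf_detection_floor}, \code{false_positive_rate} describing the
#'   simulated discovery pipelines.
#' @param seed integer seed; mandatory, all outputs are reproducible
#'   functions of it.
#' @return A \code{SimConfig} object.
#' @examples
#' cfg <- simConfig(n_sites = 50, seed = 1)
#' @export
simConfig <- function(n_pools = 8L, samples_per_pool = 200L, ploidy = 2L,
                      n_regions = 100L, region_len = 600L, n_sites = 1000L,
                      fraction_rare = 0.65,
                      rare_freq_range = c(1 / (ploidy * samples_per_pool), 0.01),
                      common_freq_range = c(0.01, 0.5),
                      fixed_pool_fraction = numeric(0),
                      depth_per_pool = 20000L,
                      base_error_rate = 0.002,
                      caller_profiles = defaultCallerProfiles(),
                      seed) {
    if (missing(seed)) stop("a seed is mandatory for reproducibility")
    new("SimConfig", n_pools = as.integer(n_pools),
        samples_per_pool = as.integer(samples_per_pool),
        ploidy = as.integer(ploidy), n_regions = as.integer(n_regions),
        region_len = as.integer(region_len), n_sites = as.integer(n_sites),
        fraction_rare = fraction_rare,
        rare_freq_range = rare_freq_range,
        common_freq_range = common_freq_range,
        fixed_pool_fraction = as.numeric(fixed_pool_fraction),
        depth_per_pool = as.integer(depth_per_pool),
        base_error_rate = base_error_rate,
        caller_profiles = caller_profiles, seed = as.integer(seed))
}

#' Default simulated discovery-pipeline roster
#'
#' Two aligners crossed with a pool-aware caller (low detection floor), a
#' generic caller, and a conservative caller, echoing the spread of
#' minor-allele-frequency sensitivity observed across published callers.
#'
#' @return data.frame with one row per simulated pipeline.
#' @export
defaultCallerProfiles <- function() {
    callers <- data.frame(
        caller = c("poolcaller", "generic", "strict"),
        maf_detection_floor = c(0.0025, 0.02, 0.05),
        false_positive_rate = c(0.02, 0.005, 0.001))
    out <- merge(data.frame(aligner = c("bowtie2", "bwa")), callers)
    data.frame(pipeline_id = paste(out$aligner, out$caller, sep = "_"),
               maf_detection_floor = out$maf_detection_floor,
               false_positive_rate = out$false_positive_rate,
               stringsAsFactors = FALSE)
}
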
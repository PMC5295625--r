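#' @include AllClasses.R variant-sites.R pool-counts.R
NULL

# rank nucleotide counts in descending order; ties broken by alphabetical
# allele order (A,C,G,T), which `order`'s stable sort gives for free when
# the input vector is in that order
rankedCounts <- function(counts) {
    counts[order(-counts)]
}

#' Sequencing-error estimate at a SNP site
#'
#' With four nucleotide counts at a site, the two top-ranked counts belong
#' to the (at most two) real alleles, while the counts ranked third and
#' fourth in descending order can only come from base-call errors. Their
#' mean estimates the per-allele sequencing-error support at the site.
#'
#' @param counts named numeric vector of at least 4 per-allele read
#'   counts (A, C, G, T at a SNP site), typically summed across pools.
#' @param rank_lo,rank_hi ranks (descending order) averaged for the
#'   estimate; defaults 3 and 4.
#' @return estimated error read count.
#' @examples
#' estimateErrors(c(A = 13028, C = 9, G = 6, T = 13))  # (9 + 6) / 2
#' @export
estimateErrors <- function(counts, rank_lo = 3L, rank_hi = 4L) {
    if (length(counts) < 4L)
        stop("error estimation needs at least 4 allele counts ",
             "(SNP sites only)")
    sorted <- rankedCounts(counts)
    mean(sorted[rank_lo:rank_hi])
}

#' Error ratio of a SNP site
#'
#' Ratio between the read count of the second-ranked allele (the putative
#' minor allele) and the sequencing-error estimate of
#' \code{\link{estimateErrors}}. A site whose minor-allele support is not
#' clearly above the error level — ratio below the threshold (default 5)
#' — is rejected as sequencing noise. When the error estimate is zero the
#' ratio is \code{+Inf} if the second-ranked count is positive (clean
#' pass) and 0 if it is also zero (no minor support at all).
#'
#' @inheritParams estimateErrors
#' @return the ratio, possibly \code{Inf}.
#' @examples
#' errorRatio(c(A = 13028, C = 9, G = 6, T = 13))  # 13 / 7.5, filtered at 5
#' @export
errorRatio <- function(counts, rank_lo = 3L, rank_hi = 4L) {
    sorted <- rankedCounts(counts)
    second <- sorted[2L]
    est <- estimateErrors(counts, rank_lo, rank_hi)
    if (est == 0) {
        if (second > 0) Inf else 0
    } else {
        unname(second / est)
    }
}

#' Remove SNPs embedded in indels
#'
#' A SNP whose position lies within the reference span
#' \code{[pos, pos + nchar(ref) - 1]} of any indel site in the merged set
#' is an unreliable call (usually an alignment artefact of the indel) and
#' is removed.
#'
#' @param sites a \linkS4class{VariantSites} object (the merged set,
#'   indels included).
#' @return list with \code{sites} (the input minus embedded SNPs) and
#'   \code{removed} (logical vector over the input).
#' @export
removeEmbeddedInIndels <- function(sites) {
    vt <- vtype(sites)
    alt_lens <- lapply(sites@alt, nchar)
    is_indel_site <- nchar(sites@ref) > 1L |
        vapply(seq_along(alt_lens), function(i)
            any(alt_lens[[i]] != nchar(sites@ref[i])), logical(1))
    removed <- rep(FALSE, length(sites))
    if (any(is_indel_site)) {
        spans <- GRanges(sites@chrom[is_indel_site],
                         IRanges(sites@pos[is_indel_site],
                                 sites@pos[is_indel_site] +
                                     nchar(sites@ref[is_indel_site]) - 1L))
        snp <- which(vt == "biallelic_SNP")
        if (length(snp)) {
            pts <- GRanges(sites@chrom[snp],
                           IRanges(sites@pos[snp], sites@pos[snp]))
            hit <- unique(S4Vectors::queryHits(findOverlaps(pts, spans)))
            removed[snp[hit]] <- TRUE
        }
    }
    list(sites = sites[!removed], removed = removed)
}

#' Apply the variant curation cascade
#'
#' Runs the downstream filters in order: (1) remove SNPs embedded in
#' indel reference spans; (2) keep biallelic SNPs only; (3) require a
#' minimum read depth (by default 10000 summed over pools); (4) require
#' presence — at least \code{min_alt_reads_presence} alternative reads —
#' in at least \code{min_pools_present} pools; (5) require an error ratio
#' of at least \code{error_ratio_threshold}, with the error statistic
#' computed on counts summed across pools (or per pool under
#' \code{aggregate_mode = "per_pool_any"}, where a site passes depth and
#' ratio if any single pool does). Surviving sites carry their per-pool
#' adjusted allele frequencies.
#'
#' @param sites a \linkS4class{VariantSites} object (merged callset).
#' @param counts a \linkS4class{PoolCounts} object covering every site.
#' @param config a \linkS4class{FilterConfig}.
#' @return list with \code{sites} (curated \code{VariantSites}),
#'   \code{counts} (matching \code{PoolCounts} rows), \code{frequencies}
#'   (adjusted frequency matrix, sites x pools), \code{report} (per-stage
#'   attrition data.frame with columns filter, sites_in, sites_removed,
#'   sites_out) and \code{kept} (logical over the input sites).
#' @export
applyCascade <- function(sites, counts, config = filterConfig()) {
    stopifnot(is(sites, "VariantSites"), is(counts, "PoolCounts"),
              is(config, "FilterConfig"))
    ckey <- paste(as.character(seqnames(rowRanges(counts))),
                  start(rowRanges(counts)), rowData(counts)$ref, sep = ":")
    skey <- siteKeys(sites, with_alt = FALSE)
    row_of <- match(skey, ckey)
    if (anyNA(row_of))
        stop("no counts for site ", skey[which(is.na(row_of))[1L]])

    n0 <- length(sites)
    alive <- rep(TRUE, n0)
    report <- data.frame(filter = character(0), sites_in = integer(0),
                         sites_removed = integer(0), sites_out = integer(0))
    note <- function(name, before, after) {
        rbind(report, data.frame(filter = name, sites_in = sum(before),
                                 sites_removed = sum(before) - sum(after),
                                 sites_out = sum(after)))
    }

    # (1) embedded in indels
    emb <- removeEmbeddedInIndels(sites)
    after <- alive & !emb$removed
    report <- note("embedded_in_indel", alive, after); alive <- after

    # (2) biallelic SNPs only
    after <- alive & vtype(sites) == "biallelic_SNP"
    report <- note("biallelic_snp", alive, after); alive <- after

    # per-pool depth and alt counts for the surviving rows
    dp <- depthMatrix(counts)[row_of, , drop = FALSE]
    altc <- assay(counts, "altCount")[row_of, , drop = FALSE]
    per_pool <- config@aggregate_mode == "per_pool_any"

    # (3) read depth
    deep <- if (per_pool)
        apply(dp >= config@min_total_depth, 1L, any, na.rm = TRUE)
    else rowSums(dp, na.rm = TRUE) >= config@min_total_depth
    after <- alive & deep
    report <- note("min_depth", alive, after); alive <- after

    # (4) present in enough pools
    present <- rowSums(altc >= config@min_alt_reads_presence,
                       na.rm = TRUE) >= config@min_pools_present
    after <- alive & present
    report <- note("min_pools", alive, after); alive <- after

    # (5) error ratio
    ratio <- siteErrorRatios(counts, config)[row_of]
    after <- alive & !is.na(ratio) & ratio >= config@error_ratio_threshold
    report <- note("error_ratio", alive, after); alive <- after

    kept_rows <- row_of[alive]
    list(sites = sites[alive],
         counts = counts[kept_rows, ],
         frequencies = adjustedFrequencies(counts)[kept_rows, ,
                                                   drop = FALSE],
         report = report,
         kept = alive)
}

# per-site error ratios; summed across pools or best pool, vectorized
siteErrorRatios <- function(counts, config = filterConfig()) {
    per_pool <- config@aggregate_mode == "per_pool_any"
    nucs <- lapply(DNA_BASES4, function(b) assay(counts, b))
    ratio_from <- function(mat4) {
        # mat4: n x 4 matrix in A,C,G,T column order
        apply(mat4, 1L, function(v) {
            if (anyNA(v)) return(NA_real_)
            errorRatio(stats::setNames(v, DNA_BASES4),
                       config@error_rank_lo, config@error_rank_hi)
        })
    }
    if (per_pool) {
        per <- vapply(seq_len(ncol(counts)), function(j)
            ratio_from(cbind(nucs[[1L]][, j], nucs[[2L]][, j],
                             nucs[[3L]][, j], nucs[[4L]][, j])),
            numeric(nrow(counts)))
        per <- matrix(per, nrow = nrow(counts))
        apply(per, 1L, function(r)
            if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE))
    } else {
        ratio_from(vapply(nucs, rowSums, numeric(nrow(counts)),
                          na.rm = FALSE))
    }
}

#' Write a filter attrition report as TSV
#'
#' @param report the \code{report} element of \code{\link{applyCascade}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeFilterReport <- function(report, file) {
    utils::write.table(report, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}

#' Write curated variants as a flat review table
#'
#' One row per curated SNP with its position, alleles, calling pipelines,
#' per-pool adjusted allele frequencies and raw nucleotide read counts —
#' a spreadsheet-friendly layout for selecting variants for follow-up.
#'
#' @param curated result of \code{\link{applyCascade}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeCuratedTable <- function(curated, file) {
    sites <- curated$sites
    pc <- curated$counts
    pools <- colData(pc)$pool_id
    df <- as.data.frame(sites)
    for (j in seq_along(pools))
        df[[paste0("freq_", pools[j])]] <- curated$frequencies[, j]
    for (b in DNA_BASES4)
        for (j in seq_along(pools))
            df[[paste0(b, "_", pools[j])]] <- assay(pc, b)[, j]
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
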
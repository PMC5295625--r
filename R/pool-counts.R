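#' @include AllClasses.R variant-sites.R
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assayNames rowData colData rowRanges
NULL

#' Construct a PoolCounts object
#'
#' @param sites a \linkS4class{VariantSites} object (one row per site).
#' @param pool_ids character vector of pool identifiers (columns).
#' @param A,C,G,T integer matrices (sites x pools) of per-nucleotide read
#'   counts at SNP sites; \code{NA} rows for indel sites.
#' @param refCount,altCount integer matrices of reads exactly matching the
#'   reference / alternative allele span; computed from the nucleotide
#'   counts at SNP sites when omitted.
#' @param n_samples,ploidy pool design, recycled over pools (defaults 200
#'   diploid samples, the geometry the pipeline was designed around).
#' @return A \linkS4class{PoolCounts} object.
#' @export
poolCounts <- function(sites, pool_ids, A, C, G, T,
                       refCount = NULL, altCount = NULL,
                       n_samples = 200L, ploidy = 2L) {
    stopifnot(is(sites, "VariantSites"))
    n <- length(sites); np <- length(pool_ids)
    shape <- function(m) {
        m <- as.matrix(m)
        stopifnot(nrow(m) == n, ncol(m) == np)
        dimnames(m) <- list(NULL, pool_ids)
        m
    }
    A <- shape(A); C <- shape(C); G <- shape(G); T <- shape(T)
    vt <- vtype(sites)
    alt1 <- predictedAltFromCounts(sites, A, C, G, T)
    if (is.null(refCount) || is.null(altCount)) {
        refCount <- matrix(NA_integer_, n, np, dimnames = list(NULL, pool_ids))
        altCount <- refCount
        snp <- vt == "biallelic_SNP" | (vt == "multiallelic" &
            nchar(sites@ref) == 1L & !is.na(alt1) & nchar(alt1) == 1L)
        nuc <- list(A = A, C = C, G = G, T = T)
        for (i in which(snp)) {
            refCount[i, ] <- nuc[[sites@ref[i]]][i, ]
            altCount[i, ] <- nuc[[alt1[i]]][i, ]
        }
    } else {
        refCount <- shape(refCount); altCount <- shape(altCount)
    }
    rr <- GRanges(sites@chrom,
                  IRanges(sites@pos, sites@pos + nchar(sites@ref) - 1L))
    mcols(rr) <- DataFrame(
        ref = sites@ref,
        alt = vapply(sites@alt, paste, character(1), collapse = ","),
        predicted_alt = alt1,
        vtype = vt)
    se <- SummarizedExperiment(
        assays = list(A = A, C = C, G = G, T = T,
                      refCount = refCount, altCount = altCount),
        rowRanges = rr,
        colData = DataFrame(pool_id = as.character(pool_ids),
                            n_samples = rep_len(as.integer(n_samples), np),
                            ploidy = rep_len(as.integer(ploidy), np),
                            row.names = pool_ids))
    new("PoolCounts", se)
}

# the single alt allele used in frequency math: the declared alt for
# biallelic sites, the highest-count non-reference nucleotide otherwise
predictedAltFromCounts <- function(sites, A, C, G, T) {
    alt1 <- vapply(sites@alt, `[[`, character(1), 1L)
    multi <- lengths(sites@alt) > 1L
    if (any(multi)) {
        tot <- cbind(A = rowSums(A, na.rm = TRUE),
                     C = rowSums(C, na.rm = TRUE),
                     G = rowSums(G, na.rm = TRUE),
                     T = rowSums(T, na.rm = TRUE))
        for (i in which(multi)) {
            snp_alts <- sites@alt[[i]][nchar(sites@alt[[i]]) == 1L]
            if (length(snp_alts))
                alt1[i] <- snp_alts[which.max(tot[i, snp_alts])]
        }
    }
    alt1
}

#' Per-site per-pool allele counts
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param i site (row) index.
#' @param pool pool (column) index or id.
#' @return named numeric vector: counts for A, C, G, T at SNP sites, or
#'   for ref and alt at indel sites.
#' @export
poolAlleleCounts <- function(x, i, pool) {
    if (rowData(x)$vtype[i] == "biallelic_indel" ||
        all(is.na(assay(x, "A")[i, ]))) {
        stats::setNames(c(assay(x, "refCount")[i, pool],
                          assay(x, "altCount")[i, pool]),
                        c("ref", "alt"))
    } else {
        stats::setNames(c(assay(x, "A")[i, pool], assay(x, "C")[i, pool],
                          assay(x, "G")[i, pool], assay(x, "T")[i, pool]),
                        DNA_BASES4)
    }
}

#' Allele frequency from pooled read counts
#'
#' The frequency of an allele in a pool is estimated as its read count
#' over the total read depth at the site. A zero-depth pool has no
#' estimate and returns \code{NA} (missing, not zero).
#'
#' @param counts named numeric vector of per-allele read counts.
#' @param allele allele whose frequency is wanted.
#' @return frequency in [0, 1], or \code{NA} at zero depth.
#' @examples
#' alleleFrequency(c(A = 989, C = 0, G = 27876, T = 0), "G")
#' @export
alleleFrequency <- function(counts, allele) {
    total <- sum(counts)
    if (is.na(total) || total == 0) return(NA_real_)
    unname(counts[[allele]] / total)
}

#' Adjusted allele frequency over the two predicted alleles
#'
#' Restricts the denominator to reads supporting the reference or the
#' alternative allele, excluding reads carrying sequencing-error alleles.
#' This is the frequency reported for curated variants.
#'
#' @param counts named numeric vector of per-allele read counts.
#' @param ref_allele,alt_allele the two predicted alleles.
#' @return \code{alt / (ref + alt)}, or \code{NA} when both counts are 0.
#' @examples
#' adjustedFrequency(c(A = 13028, C = 9, G = 6, T = 13), "A", "G")
#' @export
adjustedFrequency <- function(counts, ref_allele, alt_allele) {
    d <- counts[[ref_allele]] + counts[[alt_allele]]
    if (is.na(d) || d == 0) return(NA_real_)
    unname(counts[[alt_allele]] / d)
}

#' Matrix of adjusted allele frequencies
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @return numeric matrix (sites x pools) of
#'   \code{alt / (ref + alt)} read-count frequencies, \code{NA} where the
#'   two predicted alleles have no reads.
#' @export
adjustedFrequencies <- function(x) {
    rc <- assay(x, "refCount"); ac <- assay(x, "altCount")
    d <- rc + ac
    out <- ac / d
    out[!is.na(d) & d == 0] <- NA_real_
    out
}

#' Per-site per-pool total read depth
#'
#' Total nucleotide depth at SNP sites; ref + alt matching reads at indel
#' sites.
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @return numeric matrix (sites x pools).
#' @export
depthMatrix <- function(x) {
    d <- assay(x, "A") + assay(x, "C") + assay(x, "G") + assay(x, "T")
    ind <- is.na(d[, 1L])
    if (any(ind))
        d[ind, ] <- (assay(x, "refCount") + assay(x, "altCount"))[ind, ,
                                                                  drop = FALSE]
    d
}

#' Cross-pool allele-frequency range at one site
#'
#' Samples are pooled without regard to population structure, so the
#' allele frequency of a real variant should be stable across pools; a
#' large range between the largest and smallest per-pool estimate flags an
#' inconsistent site.
#'
#' @param freqs numeric vector of per-pool frequencies (\code{NA} for
#'   uninformative pools).
#' @param thresholds flagging thresholds (default 0.05 and 0.1; a range
#'   strictly above a threshold is flagged).
#' @return list with \code{range} (max - min, \code{NA} when fewer than 2
#'   pools are informative), \code{n_informative} and a logical
#'   \code{flags} vector named by threshold.
#' @examples
#' poolFrequencyRange(c(0.9657, 0.00046, NA))
#' @export
poolFrequencyRange <- function(freqs, thresholds = c(0.05, 0.1)) {
    f <- freqs[!is.na(freqs)]
    if (length(f) < 2L)
        return(list(range = NA_real_, n_informative = length(f),
                    flags = stats::setNames(rep(NA, length(thresholds)),
                                            paste0("gt_", thresholds))))
    r <- max(f) - min(f)
    list(range = r, n_informative = length(f),
         flags = stats::setNames(r > thresholds,
                                 paste0("gt_", thresholds)))
}

#' Cross-pool frequency-range table for every site
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param thresholds see \code{\link{poolFrequencyRange}}.
#' @return data.frame with one row per site: chrom, pos, ref, alt, the
#'   frequency range, the number of informative pools and one logical flag
#'   column per threshold.
#' @export
poolFrequencyRanges <- function(x, thresholds = c(0.05, 0.1)) {
    af <- adjustedFrequencies(x)
    n_inf <- rowSums(!is.na(af))
    rng <- apply(af, 1L, function(f) {
        f <- f[!is.na(f)]
        if (length(f) < 2L) NA_real_ else max(f) - min(f)
    })
    out <- data.frame(chrom = as.character(seqnames(rowRanges(x))),
                      pos = start(rowRanges(x)),
                      ref = rowData(x)$ref, alt = rowData(x)$alt,
                      freq_range = rng, n_informative = n_inf,
                      stringsAsFactors = FALSE)
    for (t in thresholds)
        out[[paste0("flag_gt_", t)]] <- !is.na(rng) & rng > t
    rownames(out) <- NULL
    out
}

#' Smallest detectable minor allele frequency of a pool
#'
#' A variant carried heterozygously by exactly one sample contributes one
#' alternative allele copy out of \code{ploidy * n_samples} chromosomes,
#' the theoretical frequency floor of the pool design.
#'
#' @param n_samples samples in the pool.
#' @param ploidy sample ploidy (default 2).
#' @return \code{1 / (ploidy * n_samples)}.
#' @examples
#' theoreticalMinMaf(200)  # 1/400 = 0.0025
#' @export
theoreticalMinMaf <- function(n_samples, ploidy = 2L) {
    stopifnot(n_samples >= 1L, ploidy >= 1L)
    1 / (ploidy * n_samples)
}

#' Expected minor-allele read support
#'
#' Under uniform read sampling, a minor allele at frequency \code{freq}
#' in a pool sequenced to depth \code{depth} is expected in
#' \code{depth * freq} reads.
#'
#' @param depth read depth at the site.
#' @param freq allele frequency in [0, 1].
#' @return expected read count.
#' @examples
#' expectedMinorReads(10000, 0.01)  # about 100 reads
#' @export
expectedMinorReads <- function(depth, freq) {
    stopifnot(depth >= 0, freq >= 0, freq <= 1)
    depth * freq
}

#' Count reads per allele per pool at variant sites (SAM/BAM adapter)
#'
#' Pileup-based allele counting. At SNP sites the base each read reports
#' at the position is tallied into A/C/G/T, excluding bases below
#' \code{min_base_quality}. At indel sites, reads spanning the full
#' reference span are compared with the ref and alt allele sequences
#' (insertions anchored inside the span included) and counted only on an
#' exact match; soft-clipped or partial reads are excluded.
#'
#' @param bam_files character vector of BAM/SAM paths, one per pool, named
#'   by pool id (SAM is converted transparently).
#' @param sites a \linkS4class{VariantSites} object.
#' @param min_base_quality minimum Phred base quality at the counted
#'   position (default 20).
#' @param min_mapq minimum mapping quality (default 0).
#' @param n_samples,ploidy pool design forwarded to the result.
#' @return A \linkS4class{PoolCounts} object.
#' @export
countAlleles <- function(bam_files, sites, min_base_quality = 20L,
                         min_mapq = 0L, n_samples = 200L, ploidy = 2L) {
    pool_ids <- names(bam_files)
    if (is.null(pool_ids)) pool_ids <- paste0("pool", seq_along(bam_files))
    n <- length(sites); np <- length(bam_files)
    zero <- matrix(0L, n, np, dimnames = list(NULL, pool_ids))
    nuc <- list(A = zero, C = zero, G = zero, T = zero)
    refCount <- matrix(NA_integer_, n, np, dimnames = list(NULL, pool_ids))
    altCount <- refCount
    vt <- vtype(sites)
    is_snp <- vt == "biallelic_SNP"
    is_indel <- vt == "biallelic_indel"
    for (j in seq_len(np)) {
        file <- bam_files[[j]]
        if (grepl("\\.sam$", file, ignore.case = TRUE))
            file <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                                     indexDestination = TRUE)
        bf <- Rsamtools::BamFile(file)
        sl <- Rsamtools::scanBamHeader(bf)$targets
        bad <- sites@chrom %in% names(sl) &
            (sites@pos < 1L | sites@pos > sl[sites@chrom])
        if (any(bad, na.rm = TRUE))
            stop("site outside reference bounds: ",
                 sites@chrom[which(bad)[1L]], ":",
                 sites@pos[which(bad)[1L]])
        if (any(is_snp)) {
            which_gr <- GRanges(sites@chrom[is_snp],
                                IRanges(sites@pos[is_snp],
                                        sites@pos[is_snp]))
            pu <- Rsamtools::pileup(
                bf,
                scanBamParam = Rsamtools::ScanBamParam(
                    which = GenomicRanges::reduce(which_gr)),
                pileupParam = Rsamtools::PileupParam(
                    max_depth = 10000000L,
                    min_base_quality = as.integer(min_base_quality),
                    min_mapq = as.integer(min_mapq),
                    min_nucleotide_depth = 0L,
                    distinguish_strands = FALSE,
                    distinguish_nucleotides = TRUE,
                    include_deletions = FALSE,
                    include_insertions = FALSE))
            if (nrow(pu)) {
                key <- paste(pu$seqnames, pu$pos)
                skey <- paste(sites@chrom, sites@pos)
                for (b in DNA_BASES4) {
                    sel <- pu$nucleotide == b
                    m <- match(skey, key[sel])
                    hit <- which(is_snp & !is.na(m))
                    nuc[[b]][hit, j] <- pu$count[sel][m[hit]]
                }
            }
        }
        if (any(is_indel)) {
            cnt <- countIndelAlleles(file, sites[which(is_indel)],
                                     min_mapq = min_mapq)
            refCount[is_indel, j] <- cnt$ref
            altCount[is_indel, j] <- cnt$alt
        }
    }
    poolCounts(sites, pool_ids, nuc$A, nuc$C, nuc$G, nuc$T,
               refCount = refCount, altCount = altCount,
               n_samples = n_samples, ploidy = ploidy)
}

# exact-span indel allele counting: reconstruct each spanning read's
# implied haplotype over [pos, pos + nchar(ref) - 1] from its CIGAR
countIndelAlleles <- function(bam, sites, min_mapq = 0L) {
    n <- length(sites)
    refc <- integer(n); altc <- integer(n)
    which_gr <- GRanges(sites@chrom,
                        IRanges(sites@pos,
                                sites@pos + nchar(sites@ref) - 1L))
    param <- Rsamtools::ScanBamParam(
        what = c("pos", "cigar", "seq", "mapq"),
        which = which_gr)
    res <- Rsamtools::scanBam(bam, param = param)
    for (i in seq_len(n)) {
        r <- res[[i]]
        if (!length(r$pos)) next
        keep <- !is.na(r$mapq) & r$mapq >= min_mapq
        w_start <- sites@pos[i]
        w_end <- w_start + nchar(sites@ref[i]) - 1L
        alt <- sites@alt[[i]][1L]
        for (k in which(keep)) {
            hap <- readWindowHaplotype(r$pos[k], r$cigar[k],
                                       as.character(r$seq[k]),
                                       w_start, w_end)
            if (is.na(hap)) next
            if (hap == sites@ref[i]) refc[i] <- refc[i] + 1L
            else if (hap == alt) altc[i] <- altc[i] + 1L
        }
    }
    list(ref = refc, alt = altc)
}

# implied read haplotype over reference window [w_start, w_end]; NA when
# the read does not fully span the window with aligned bases
readWindowHaplotype <- function(pos, cigar, seq, w_start, w_end) {
    ops <- GenomicAlignments::explodeCigarOps(cigar)[[1L]]
    lens <- GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
    ref_pos <- pos; q_pos <- 1L
    out <- ""
    covered_lo <- Inf; covered_hi <- -Inf
    for (t in seq_along(ops)) {
        op <- ops[t]; len <- lens[t]
        if (op %in% c("M", "=", "X")) {
            lo <- ref_pos; hi <- ref_pos + len - 1L
            covered_lo <- min(covered_lo, lo); covered_hi <- max(covered_hi, hi)
            a <- max(lo, w_start); b <- min(hi, w_end)
            if (a <= b)
                out <- paste0(out, substr(seq, q_pos + (a - lo),
                                          q_pos + (b - lo)))
            ref_pos <- ref_pos + len; q_pos <- q_pos + len
        } else if (op == "D" || op == "N") {
            covered_lo <- min(covered_lo, ref_pos)
            covered_hi <- max(covered_hi, ref_pos + len - 1L)
            ref_pos <- ref_pos + len
        } else if (op == "I") {
            anchor <- ref_pos - 1L
            if (anchor >= w_start && anchor <= w_end)
                out <- paste0(out, substr(seq, q_pos, q_pos + len - 1L))
            q_pos <- q_pos + len
        } else if (op == "S") {
            q_pos <- q_pos + len
        }
        # H and P consume nothing relevant
    }
    if (covered_lo > w_start || covered_hi < w_end) return(NA_character_)
    out
}

#' Read a long-format pool counts table
#'
#' Expects columns \code{chrom}, \code{pos}, \code{ref}, \code{alt},
#' \code{pool_id}, \code{A}, \code{C}, \code{G}, \code{T} and optionally
#' \code{ref_count}, \code{alt_count} for indel sites.
#'
#' @param file path to the TSV.
#' @param n_samples,ploidy pool design, recycled over pools.
#' @return A \linkS4class{PoolCounts} object.
#' @export
readPoolCounts <- function(file, n_samples = 200L, ploidy = 2L) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt", "pool_id", "A", "C", "G", "T")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("counts table missing column(s): ",
                           paste(miss, collapse = ", "))
    skey <- paste(df$chrom, df$pos, df$ref, sep = ":")
    usite <- !duplicated(skey)
    pool_ids <- sort(unique(df$pool_id))
    sites <- VariantSites(df$chrom[usite], df$pos[usite], df$ref[usite],
                          strsplit(df$alt[usite], ","))
    ri <- match(skey, skey[usite])
    ci <- match(df$pool_id, pool_ids)
    n <- sum(usite); np <- length(pool_ids)
    grab <- function(col, default = 0L) {
        m <- matrix(default, n, np, dimnames = list(NULL, pool_ids))
        if (!is.null(df[[col]])) m[cbind(ri, ci)] <- df[[col]]
        m
    }
    has_rc <- all(c("ref_count", "alt_count") %in% colnames(df))
    poolCounts(sites, pool_ids, grab("A"), grab("C"), grab("G"), grab("T"),
               refCount = if (has_rc) grab("ref_count", NA_integer_),
               altCount = if (has_rc) grab("alt_count", NA_integer_),
               n_samples = n_samples, ploidy = ploidy)
}

#' Write pool counts as a long-format TSV
#'
#' @param x a \linkS4class{PoolCounts} object.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writePoolCounts <- function(x, file) {
    n <- nrow(x); np <- ncol(x)
    rd <- rowData(x)
    df <- data.frame(
        chrom = rep(as.character(seqnames(rowRanges(x))), np),
        pos = rep(start(rowRanges(x)), np),
        ref = rep(rd$ref, np), alt = rep(rd$alt, np),
        pool_id = rep(colData(x)$pool_id, each = n),
        A = as.vector(assay(x, "A")), C = as.vector(assay(x, "C")),
        G = as.vector(assay(x, "G")), T = as.vector(assay(x, "T")),
        ref_count = as.vector(assay(x, "refCount")),
        alt_count = as.vector(assay(x, "altCount")))
    df$depth <- as.vector(depthMatrix(x))
    utils::write.table(df, file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    invisible(file)
}
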
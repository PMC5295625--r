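#' @include AllClasses.R
NULL

#' Construct an aligned-fragment table
#'
#' Fragments are the genomic spans of sequenced read pairs after alignment.
#' Each fragment carries its pool of origin and two QC flags: whether the
#' pair aligned with the expected distance and orientation
#' (\code{proper_pair}) and whether it aligned to a unique location
#' (\code{unique}). Only properly paired, uniquely mapped fragments are
#' eligible for region assignment; the others still count in the capture
#' rate denominator.
#'
#' @param chrom,start,end fragment span, 1-based inclusive.
#' @param pool_id pool of origin.
#' @param proper_pair,unique logical QC flags (default \code{TRUE}).
#' @param max_frag_len maximum allowed fragment length in bp (default 800,
#'   the usual aligner insert-size cap for 600 bp amplicons).
#' @return A \linkS4class{GRanges} with metadata columns \code{pool_id},
#'   \code{proper_pair}, \code{unique}.
#' @examples
#' alignedFragments("chr1", 101, 700, "pool1")
#' @export
alignedFragments <- function(chrom, start, end, pool_id,
                             proper_pair = TRUE, unique = TRUE,
                             max_frag_len = 800L) {
    start <- as.integer(start); end <- as.integer(end)
    if (any(is.na(start) | is.na(end) | end < start))
        stop("malformed fragment interval (need start <= end)")
    len <- end - start + 1L
    if (any(len > max_frag_len))
        stop("fragment length exceeds max_frag_len (", max_frag_len, ")")
    gr <- GRanges(chrom, IRanges(start, end))
    n <- length(gr)
    mcols(gr) <- DataFrame(
        pool_id = rep_len(as.character(pool_id), n),
        proper_pair = rep_len(as.logical(proper_pair), n),
        unique = rep_len(as.logical(unique), n))
    gr
}

#' Assign fragments to target regions by reciprocal overlap
#'
#' A fragment is assigned to a region when the overlap covers at least
#' \code{min_reciprocal} of the fragment length \emph{and} at least
#' \code{min_reciprocal} of the region length (both boundaries inclusive).
#' If several regions qualify, the one with the larger product of the two
#' overlap fractions wins; an exact tie leaves the fragment unassigned.
#' Fragments that are not properly paired or not uniquely mapped are never
#' assigned, and fragments on chromosomes absent from the region set are
#' simply unassigned, not an error.
#'
#' @param frags fragments from \code{\link{alignedFragments}}.
#' @param regions a \linkS4class{TargetRegions} object.
#' @param min_reciprocal reciprocal overlap threshold (default 0.9).
#' @return character vector parallel to \code{frags}: the assigned
#'   \code{region_id} or \code{NA}.
#' @examples
#' tr <- TargetRegions("r1", "chr1", 101, 700)
#' fr <- alignedFragments("chr1", 101, 700, "pool1")
#' assignFragments(fr, tr)
#' @export
assignFragments <- function(frags, regions, min_reciprocal = 0.9) {
    stopifnot(is(regions, "TargetRegions"))
    out <- rep(NA_character_, length(frags))
    eligible <- mcols(frags)$proper_pair & mcols(frags)$unique
    hits <- suppressWarnings(
        findOverlaps(frags, regions, ignore.strand = TRUE))
    if (!length(hits)) return(out)
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    ov <- width(pintersect(granges(frags)[qh], granges(regions)[sh]))
    frac_f <- ov / width(frags)[qh]
    frac_r <- ov / width(regions)[sh]
    ok <- eligible[qh] & frac_f >= min_reciprocal & frac_r >= min_reciprocal
    if (!any(ok)) return(out)
    qh <- qh[ok]; sh <- sh[ok]
    score <- (frac_f * frac_r)[ok]
    # per fragment: best-scoring region; exact tie for the top score -> NA
    o <- order(qh, -score)
    qh <- qh[o]; sh <- sh[o]; score <- score[o]
    first <- !duplicated(qh)
    best <- score[first]
    second <- rep(-Inf, sum(first))
    runs <- rle(qh)
    has2 <- runs$lengths >= 2L
    idx2 <- cumsum(runs$lengths) - runs$lengths + 2L
    second[has2] <- score[idx2[has2]]
    tie <- second == best
    assigned <- mcols(regions)$region_id[sh[first]]
    assigned[tie] <- NA_character_
    out[qh[first]] <- assigned
    out
}

#' Capture success rate of an amplicon experiment
#'
#' Fraction of sequenced fragments reliably assigned to a single target
#' region under the reciprocal-overlap criterion; unassignable fragments
#' (off-target, improper pairs, multi-mappers, ambiguous) count in the
#' denominator.
#'
#' @inheritParams assignFragments
#' @return fraction in [0, 1].
#' @export
captureRate <- function(frags, regions, min_reciprocal = 0.9) {
    if (!length(frags)) stop("no fragments")
    mean(!is.na(assignFragments(frags, regions, min_reciprocal)))
}

#' Per-region per-pool fragment depth with low-coverage flags
#'
#' Counts assigned fragments for every (region, pool) combination, zeros
#' included, and flags combinations whose count falls strictly below
#' \code{min_fragments} — these mark failed or weak primers in a pool.
#'
#' @inheritParams assignFragments
#' @param min_fragments flagging threshold (default 20); a (region, pool)
#'   with count < threshold is flagged.
#' @param pools optional character vector of pool ids to tabulate over
#'   (defaults to the pools present in \code{frags}).
#' @return list with \code{depth} (integer matrix, regions x pools),
#'   \code{flags} (data.frame of flagged region/pool pairs with counts,
#'   sorted by region_id) and \code{assignments} (the per-fragment region
#'   ids).
#' @export
regionDepthTable <- function(frags, regions, min_fragments = 20L,
                             pools = NULL, min_reciprocal = 0.9) {
    asn <- assignFragments(frags, regions, min_reciprocal)
    if (is.null(pools)) pools <- sort(unique(mcols(frags)$pool_id))
    rid <- mcols(regions)$region_id
    depth <- table(factor(asn, levels = rid),
                   factor(mcols(frags)$pool_id, levels = pools))
    depth <- matrix(as.integer(depth), nrow = length(rid),
                    dimnames = list(rid, pools))
    low <- which(depth < min_fragments, arr.ind = TRUE)
    flags <- data.frame(region_id = rownames(depth)[low[, 1L]],
                        pool_id = colnames(depth)[low[, 2L]],
                        count = depth[low], stringsAsFactors = FALSE)
    flags <- flags[order(flags$region_id, flags$pool_id), , drop = FALSE]
    rownames(flags) <- NULL
    list(depth = depth, flags = flags, assignments = asn)
}

#' Expected per-base read depth of an amplicon panel
#'
#' Under the idealisation that every fragment reads its entire region and
#' fragments distribute evenly over regions, the expected depth per
#' targeted base pair is simply fragments per region.
#'
#' @param total_fragments fragments sequenced (per pool).
#' @param n_regions number of target regions.
#' @return expected per-base depth.
#' @examples
#' expectedDepth(2.5e6, 121)   # about 20,000x
#' @export
expectedDepth <- function(total_fragments, n_regions) {
    if (n_regions <= 0) stop("n_regions must be positive")
    total_fragments / n_regions
}

#' Central coverage gap of a trimmed amplicon
#'
#' Quality trimming shortens the two reads of a pair; when the trimmed
#' reads no longer tile the amplicon, its central part goes unsequenced.
#'
#' @param amplicon_len amplicon length in bp.
#' @param read1_len,read2_len trimmed read lengths in bp.
#' @return uncovered central bp (0 when the reads tile or overlap).
#' @examples
#' coverageGap(600, 240, 170)  # 190 bp uncovered
#' @export
coverageGap <- function(amplicon_len, read1_len, read2_len) {
    stopifnot(amplicon_len > 0, read1_len > 0, read2_len > 0)
    pmax(0, amplicon_len - read1_len - read2_len)
}

#' Read target regions from BED plus a metadata sidecar
#'
#' The BED file (0-based half-open, converted on import) provides the
#' intervals and region ids (name column); the optional tab-separated
#' sidecar adds \code{primer_pair} and \code{expected_amplicon_len} keyed
#' by \code{region_id}.
#'
#' @param bed_file path to a BED file.
#' @param meta_file optional path to the TSV sidecar.
#' @return A \linkS4class{TargetRegions} object.
#' @export
readTargetRegions <- function(bed_file, meta_file = NULL) {
    gr <- rtracklayer::import(bed_file, format = "BED")
    rid <- if (!is.null(mcols(gr)$name)) as.character(mcols(gr)$name)
           else paste0("region", seq_along(gr))
    primer <- rid
    explen <- width(gr)
    if (!is.null(meta_file)) {
        meta <- utils::read.delim(meta_file, stringsAsFactors = FALSE)
        m <- match(rid, meta$region_id)
        if (anyNA(m)) stop("regions missing from metadata: ",
                           paste(rid[is.na(m)], collapse = ", "))
        if (!is.null(meta$primer_pair)) primer <- meta$primer_pair[m]
        if (!is.null(meta$expected_amplicon_len))
            explen <- meta$expected_amplicon_len[m]
    }
    TargetRegions(rid, as.character(seqnames(gr)), start(gr), end(gr),
                  primer_pair = primer, expected_amplicon_len = explen)
}

#' Write target regions as BED plus a metadata sidecar
#'
#' @param regions a \linkS4class{TargetRegions} object.
#' @param bed_file output BED path.
#' @param meta_file optional output TSV sidecar path.
#' @return invisibly, \code{bed_file}.
#' @export
writeTargetRegions <- function(regions, bed_file, meta_file = NULL) {
    gr <- granges(regions)
    mcols(gr)$name <- mcols(regions)$region_id
    rtracklayer::export(gr, bed_file, format = "BED")
    if (!is.null(meta_file)) {
        utils::write.table(
            data.frame(region_id = mcols(regions)$region_id,
                       primer_pair = mcols(regions)$primer_pair,
                       expected_amplicon_len =
                           mcols(regions)$expected_amplicon_len),
            meta_file, sep = "\t", quote = FALSE, row.names = FALSE)
    }
    invisible(bed_file)
}

#' Read an aligned-fragment table from TSV
#'
#' Expects columns \code{chrom}, \code{start}, \code{end}, \code{pool_id},
#' \code{proper_pair}, \code{unique} (1-based inclusive coordinates).
#'
#' @param file path to the TSV.
#' @param max_frag_len see \code{\link{alignedFragments}}.
#' @return fragments as returned by \code{\link{alignedFragments}}.
#' @export
readFragments <- function(file, max_frag_len = 800L) {
    df <- utils::read.delim(file, stringsAsFactors = FALSE)
    need <- c("chrom", "start", "end", "pool_id", "proper_pair", "unique")
    miss <- setdiff(need, colnames(df))
    if (length(miss)) stop("fragment table missing column(s): ",
                           paste(miss, collapse = ", "))
    alignedFragments(df$chrom, df$start, df$end, df$pool_id,
                     as.logical(df$proper_pair), as.logical(df$unique),
                     max_frag_len = max_frag_len)
}

#' Write an aligned-fragment table to TSV
#'
#' @param frags fragments from \code{\link{alignedFragments}}.
#' @param file output path.
#' @return invisibly, \code{file}.
#' @export
writeFragments <- function(frags, file) {
    utils::write.table(
        data.frame(chrom = as.character(seqnames(frags)),
                   start = start(frags), end = end(frags),
                   pool_id = mcols(frags)$pool_id,
                   proper_pair = mcols(frags)$proper_pair,
                   unique = mcols(frags)$unique),
        file, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(file)
}

#' Derive fragments from paired-end alignments (SAM/BAM adapter)
#'
#' Reads paired alignments and emits one fragment per read pair spanning
#' from the leftmost to the rightmost aligned base. A pair is flagged
#' \code{proper_pair} from its SAM flag and \code{unique} when both mates
#' reach \code{min_mapq}.
#'
#' @param file path to a BAM (or SAM, converted transparently) file.
#' @param pool_id pool of origin for every fragment in the file.
#' @param min_mapq minimum mapping quality for a unique alignment
#'   (default 20).
#' @param max_frag_len see \code{\link{alignedFragments}}; longer pairs are
#'   dropped as aligner artefacts.
#' @return fragments as returned by \code{\link{alignedFragments}}.
#' @export
fragmentsFromBam <- function(file, pool_id, min_mapq = 20L,
                             max_frag_len = 800L) {
    if (grepl("\\.sam$", file, ignore.case = TRUE)) {
        bam <- Rsamtools::asBam(file, tempfile(), overwrite = TRUE,
                                indexDestination = TRUE)
        file <- bam
    }
    param <- Rsamtools::ScanBamParam(what = c("mapq", "flag"))
    pairs <- GenomicAlignments::readGAlignmentPairs(file, param = param,
                                                    strandMode = 0)
    if (!length(pairs))
        return(alignedFragments(character(0), integer(0), integer(0),
                                character(0)))
    f <- GenomicAlignments::first(pairs)
    s <- GenomicAlignments::second(pairs)
    frag_start <- pmin(start(f), start(s))
    frag_end <- pmax(end(f), end(s))
    keep <- (frag_end - frag_start + 1L) <= max_frag_len
    proper <- bitwAnd(mcols(f)$flag, 2L) > 0L
    uniq <- mcols(f)$mapq >= min_mapq & mcols(s)$mapq >= min_mapq
    alignedFragments(as.character(seqnames(f))[keep], frag_start[keep],
                     frag_end[keep], pool_id, proper[keep], uniq[keep],
                     max_frag_len = max_frag_len)
}
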
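# Brute-force oracles and fixture builders shared across tests.
# Oracles deliberately use naive scalar loops, independent of the
# vectorized/interval-tree code paths they check.

# O(F x R) reciprocal-overlap assignment scan
bruteAssign <- function(frags, regions, min_reciprocal = 0.9) {
    fdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(frags)),
                      start = GenomicRanges::start(frags),
                      end = GenomicRanges::end(frags),
                      proper = S4Vectors::mcols(frags)$proper_pair,
                      uniq = S4Vectors::mcols(frags)$unique)
    rdf <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                      start = GenomicRanges::start(regions),
                      end = GenomicRanges::end(regions),
                      id = S4Vectors::mcols(regions)$region_id)
    out <- rep(NA_character_, nrow(fdf))
    for (i in seq_len(nrow(fdf))) {
        if (!fdf$proper[i] || !fdf$uniq[i]) next
        best <- -Inf; best_id <- NA_character_; tie <- FALSE
        for (j in seq_len(nrow(rdf))) {
            if (fdf$chrom[i] != rdf$chrom[j]) next
            ov <- min(fdf$end[i], rdf$end[j]) -
                max(fdf$start[i], rdf$start[j]) + 1L
            if (ov <= 0) next
            ff <- ov / (fdf$end[i] - fdf$start[i] + 1L)
            fr <- ov / (rdf$end[j] - rdf$start[j] + 1L)
            if (ff >= min_reciprocal && fr >= min_reciprocal) {
                sc <- ff * fr
                if (sc > best) { best <- sc; best_id <- rdf$id[j]; tie <- FALSE }
                else if (sc == best) tie <- TRUE
            }
        }
        if (!tie && is.finite(best)) out[i] <- best_id
    }
    out
}

# apply a (pos, ref, alt) edit to a reference string
applyEdit <- function(refstr, pos, ref, alt) {
    stopifnot(substr(refstr, pos, pos + nchar(ref) - 1L) == ref)
    paste0(substr(refstr, 1L, pos - 1L), alt,
           substr(refstr, pos + nchar(ref), nchar(refstr)))
}

# naive per-read allele count from raw SAM text: pure M-cigar reads only
bruteSamBaseCounts <- function(sam_lines, pos, min_bq = 20L) {
    counts <- c(A = 0L, C = 0L, G = 0L, T = 0L)
    for (l in sam_lines) {
        if (startsWith(l, "@")) next
        f <- strsplit(l, "\t")[[1L]]
        rpos <- as.integer(f[4L]); seq <- f[10L]; qual <- f[11L]
        stopifnot(grepl("^[0-9]+M$", f[6L]))
        off <- pos - rpos + 1L
        if (off < 1L || off > nchar(seq)) next
        bq <- utf8ToInt(substr(qual, off, off)) - 33L
        if (bq < min_bq) next
        b <- substr(seq, off, off)
        if (b %in% names(counts)) counts[b] <- counts[b] + 1L
    }
    counts
}

# hand-rolled SAM writer (single-end reads, given cigars)
writeToySam <- function(file, chrom, chrom_len, reads) {
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               paste0("@SQ\tSN:", chrom, "\tLN:", chrom_len))
    for (i in seq_len(nrow(reads))) {
        qual <- reads$qual[i]
        if (is.na(qual) || !nzchar(qual))
            qual <- strrep("I", nchar(reads$seq[i]))
        lines <- c(lines, paste(paste0("r", i), "0", chrom, reads$pos[i],
                                "60", reads$cigar[i], "*", "0", "0",
                                reads$seq[i], qual, sep = "\t"))
    }
    o <- order(as.integer(reads$pos))
    header <- lines[1:2]
    body <- lines[-(1:2)][o]
    writeLines(c(header, body), file)
    file
}

# toy plus-strand gene over a given reference window
toyGene <- function(gene_id, chrom, cds_start, cds_len, strand = "+",
                    phase = 0L) {
    transcriptModel(gene_id, paste0(gene_id, ".1"), chrom, strand,
                    exons = data.frame(start = cds_start,
                                       end = cds_start + cds_len - 1L),
                    cds = data.frame(start = cds_start,
                                     end = cds_start + cds_len - 1L,
                                     phase = phase))
}

# random DNA string
randomDna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

# write a minimal VCF for a set of atoms
writeToyVcf <- function(file, chrom, pos, ref, alt) {
    hdr <- c("##fileformat=VCFv4.2",
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO"), collapse = "\t"))
    body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", sep = "\t")
    writeLines(c(hdr, body), file)
    file
}
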
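#' @include AllClasses.R variant-sites.R
#' @importFrom Biostrings DNAStringSet readDNAStringSet subseq
NULL

# fetch reference bases [start, end] (1-based) from a DNAStringSet
refBases <- function(reference, chrom, start, end) {
    if (!chrom %in% names(reference))
        stop("chromosome ", chrom, " absent from reference")
    if (start < 1L || end > length(reference[[chrom]]))
        stop("site outside reference bounds: ", chrom, ":", start, "-", end)
    as.character(subseq(reference[[chrom]], start, end))
}

#' Normalize variant representations
#'
#' Left-aligns and minimally represents each (pos, ref, alt) pair against
#' the reference: shared trailing bases are trimmed (extending to the left
#' with reference sequence when an allele would become empty) and shared
#' leading bases are trimmed while both alleles keep at least one base.
#' Distinct textual representations of the same indel map to one canonical
#' form, which makes callsets from different callers comparable.
#'
#' @param chrom,pos,ref,alt parallel vectors describing one allele pair per
#'   element (multiallelic records must be split beforehand).
#' @param reference a named \linkS4class{DNAStringSet}.
#' @return data.frame with normalized \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}.
#' @examples
#' ref <- Biostrings::DNAStringSet(c(chr1 = "TTGACACACGG"))
#' # two representations of the same 2 bp deletion
#' normalizeVariants("chr1", 4L, "ACA", "A", ref)
#' normalizeVariants("chr1", 6L, "ACA", "A", ref)
#' @export
normalizeVariants <- function(chrom, pos, ref, alt, reference) {
    n <- length(pos)
    chrom <- rep_len(as.character(chrom), n)
    ref <- rep_len(toupper(ref), n); alt <- rep_len(toupper(alt), n)
    out_pos <- as.integer(pos); out_ref <- ref; out_alt <- alt
    for (i in seq_len(n)) {
        p <- out_pos[i]; r <- out_ref[i]; a <- out_alt[i]
        if (r == a) stop("ref equals alt at ", chrom[i], ":", p)
        repeat {
            nr <- nchar(r); na <- nchar(a)
            if (nr > 0L && na > 0L &&
                substr(r, nr, nr) == substr(a, na, na)) {
                if (nr == 1L || na == 1L) {
                    if (p == 1L) break
                    b <- refBases(reference, chrom[i], p - 1L, p - 1L)
                    r <- paste0(b, r); a <- paste0(b, a); p <- p - 1L
                    nr <- nr + 1L; na <- na + 1L
                }
                r <- substr(r, 1L, nr - 1L)
                a <- substr(a, 1L, na - 1L)
            } else break
        }
        while (nchar(r) > 1L && nchar(a) > 1L &&
               substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
            r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a))
            p <- p + 1L
        }
        out_pos[i] <- p; out_ref[i] <- r; out_alt[i] <- a
    }
    data.frame(chrom = chrom, pos = out_pos, ref = out_ref, alt = out_alt,
               stringsAsFactors = FALSE)
}

# fuse normalized atoms (one row per chrom/pos/ref/alt, with a list column
# of pipelines) into a VariantSites object keyed by (chrom, pos, ref)
fuseAtoms <- function(atoms) {
    if (!nrow(atoms))
        return(VariantSites(character(0), integer(0), character(0),
                            CharacterList()))
    key <- paste(atoms$chrom, atoms$pos, atoms$ref, sep = ":")
    grp <- split(seq_len(nrow(atoms)), key)
    # preserve genomic order
    first <- vapply(grp, `[[`, integer(1), 1L)
    grp <- grp[order(atoms$chrom[first], atoms$pos[first], atoms$ref[first])]
    chrom <- vapply(grp, function(i) atoms$chrom[i[1L]], character(1))
    pos <- vapply(grp, function(i) atoms$pos[i[1L]], integer(1))
    ref <- vapply(grp, function(i) atoms$ref[i[1L]], character(1))
    alt <- CharacterList(lapply(grp, function(i) sort(unique(atoms$alt[i]))))
    prov <- CharacterList(lapply(grp, function(i)
        sort(unique(unlist(atoms$pipelines[i])))))
    VariantSites(unname(chrom), unname(pos), unname(ref),
                 unname(alt), unname(prov))
}

#' Read a discovery pipeline's VCF as normalized variant sites
#'
#' Parses a VCF (4.0-4.3, plain or bgzipped), splits multi-allelic records
#' into single-allele atoms, left-aligns each atom against the reference
#' when one is supplied, and re-fuses atoms sharing (chrom, pos, ref) into
#' sites. Every site carries \code{pipeline_id} as its provenance. Unknown
#' or absent header fields are tolerated; an allele whose REF disagrees
#' with the reference sequence is a hard error naming the record.
#'
#' @param file path to the VCF.
#' @param pipeline_id identifier of the discovery pipeline, conventionally
#'   \code{"<aligner>_<caller>"}.
#' @param reference optional named \linkS4class{DNAStringSet} used for REF
#'   checking and indel left-alignment.
#' @return A \linkS4class{VariantSites} object.
#' @export
readCallset <- function(file, pipeline_id, reference = NULL) {
    vcf <- withCallingHandlers(
        VariantAnnotation::readVcf(file),
        warning = function(w) {
            message("VCF reader tolerated: ", conditionMessage(w))
            invokeRestart("muffleWarning")
        })
    rr <- SummarizedExperiment::rowRanges(vcf)
    if (!length(rr))
        return(VariantSites(character(0), integer(0), character(0),
                            CharacterList()))
    alts <- VariantAnnotation::alt(vcf)
    nalt <- lengths(alts)
    atoms <- data.frame(
        chrom = rep(as.character(seqnames(rr)), nalt),
        pos = rep(start(rr), nalt),
        ref = rep(as.character(VariantAnnotation::ref(vcf)), nalt),
        alt = as.character(unlist(alts)),
        stringsAsFactors = FALSE)
    keep <- !grepl("[^ACGT]", atoms$alt) & !grepl("[^ACGT]", atoms$ref)
    if (any(!keep))
        message("dropping ", sum(!keep),
                " record(s) with symbolic or non-ACGT alleles")
    atoms <- atoms[keep, , drop = FALSE]
    if (!is.null(reference)) {
        obs <- mapply(function(ch, p, r)
            refBases(reference, ch, p, p + nchar(r) - 1L),
            atoms$chrom, atoms$pos, atoms$ref)
        bad <- which(obs != atoms$ref)
        if (length(bad))
            stop("REF mismatch with reference at ", atoms$chrom[bad[1L]],
                 ":", atoms$pos[bad[1L]], " (VCF says ", atoms$ref[bad[1L]],
                 ", reference says ", obs[bad[1L]], ")")
        norm <- normalizeVariants(atoms$chrom, atoms$pos, atoms$ref,
                                  atoms$alt, reference)
        atoms[c("chrom", "pos", "ref", "alt")] <- norm
    }
    atoms <- unique(atoms)
    atoms$pipelines <- rep(list(pipeline_id), nrow(atoms))
    fuseAtoms(atoms)
}

#' Write variant sites as a VCF
#'
#' Emits a minimal VCF 4.2 with an INFO field \code{PIPES} listing the
#' calling pipelines per site and, optionally, per-pool adjusted allele
#' frequencies (\code{PAF}) and raw nucleotide read counts (\code{PACGT})
#' for curated sites.
#'
#' @param sites a \linkS4class{VariantSites} object.
#' @param file output path.
#' @param pool_freqs optional numeric matrix (sites x pools) of adjusted
#'   allele frequencies.
#' @param pool_counts optional \linkS4class{PoolCounts} aligned to
#'   \code{sites}, whose ACGT counts are embedded.
#' @return invisibly, \code{file}.
#' @export
writeSitesVcf <- function(sites, file, pool_freqs = NULL,
                          pool_counts = NULL) {
    hdr <- c("##fileformat=VCFv4.2",
             paste0("##INFO=<ID=PIPES,Number=.,Type=String,",
                    "Description=\"Discovery pipelines calling the site\">"))
    if (!is.null(pool_freqs))
        hdr <- c(hdr, paste0("##INFO=<ID=PAF,Number=.,Type=Float,",
                             "Description=\"Adjusted allele frequency per ",
                             "pool (", paste(colnames(pool_freqs),
                                             collapse = ","), ")\">"))
    if (!is.null(pool_counts))
        hdr <- c(hdr, paste0("##INFO=<ID=PACGT,Number=.,Type=String,",
                             "Description=\"Per-pool A:C:G:T read counts\">"))
    hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                          "FILTER", "INFO"), collapse = "\t"))
    n <- length(sites)
    info <- vapply(seq_len(n), function(i) {
        f <- paste0("PIPES=", paste(sites@provenance[[i]], collapse = ","))
        if (!is.null(pool_freqs))
            f <- paste0(f, ";PAF=", paste(
                ifelse(is.na(pool_freqs[i, ]), ".",
                       sprintf("%.6g", pool_freqs[i, ])), collapse = ","))
        if (!is.null(pool_counts)) {
            acgt <- vapply(seq_len(ncol(pool_counts)), function(j)
                paste(poolAlleleCounts(pool_counts, i, j)[DNA_BASES4],
                      collapse = ":"), character(1))
            f <- paste0(f, ";PACGT=", paste(acgt, collapse = ","))
        }
        f
    }, character(1))
    body <- paste(sites@chrom, sites@pos, ".", sites@ref,
                  vapply(sites@alt, paste, character(1), collapse = ","),
                  ".", "PASS", if (n) info else character(0), sep = "\t")
    writeLines(c(hdr, body), file)
    invisible(file)
}

#' Read a reference genome from FASTA
#'
#' Thin wrapper around \code{\link[Biostrings]{readDNAStringSet}} that
#' strips FASTA description text so sequences are keyed by bare
#' chromosome name.
#'
#' @param file path to a FASTA file.
#' @return named \linkS4class{DNAStringSet}.
#' @export
readReference <- function(file) {
    ref <- readDNAStringSet(file)
    names(ref) <- sub("\\s.*$", "", names(ref))
    ref
}
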
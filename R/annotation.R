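#' @include AllClasses.R variant-sites.R vcf-io.R
#' @importFrom Biostrings GENETIC_CODE reverseComplement DNAString
NULL

#' Gene models for consequence annotation
#'
#' A \code{GeneModels} object holds transcript structures: per transcript
#' its gene, chromosome, strand, exon intervals and CDS segments with
#' phase. Coordinates are 1-based inclusive.
#'
#' @export
setClass("GeneModels", representation(transcripts = "list"))

setMethod("show", "GeneModels", function(object) {
    tx <- object@transcripts
    cat("GeneModels with", length(tx), "transcript(s) in",
        length(unique(vapply(tx, `[[`, character(1), "gene_id"))),
        "gene(s)\n")
})

#' @describeIn GeneModels-class number of transcripts.
#' @param x a GeneModels object.
#' @export
setMethod("length", "GeneModels", function(x) length(x@transcripts))

#' Construct a single transcript model
#'
#' @param gene_id,transcript_id identifiers.
#' @param chrom chromosome name.
#' @param strand \code{"+"} or \code{"-"}.
#' @param exons data.frame with columns \code{start}, \code{end}
#'   (1-based inclusive); must be non-overlapping.
#' @param cds data.frame with columns \code{start}, \code{end},
#'   \code{phase} (0, 1 or 2: bases to skip before the first complete
#'   codon of the segment); every CDS segment must lie within an exon and
#'   the spliced CDS length net of the initial phase must divide into
#'   codons.
#' @return a transcript record (list) for \code{\link{geneModels}}.
#' @export
transcriptModel <- function(gene_id, transcript_id, chrom, strand,
                            exons, cds) {
    stopifnot(strand %in% c("+", "-"))
    exons <- exons[order(exons$start), , drop = FALSE]
    if (nrow(exons) > 1L &&
        any(exons$start[-1L] <= exons$end[-nrow(exons)]))
        stop("overlapping exons in transcript ", transcript_id)
    if (is.null(cds$phase)) cds$phase <- 0L
    cds <- cds[order(cds$start), , drop = FALSE]
    in_exon <- vapply(seq_len(nrow(cds)), function(i)
        any(cds$start[i] >= exons$start & cds$end[i] <= exons$end),
        logical(1))
    if (!all(in_exon))
        stop("CDS outside exons in transcript ", transcript_id)
    ord <- orderCds(cds, strand)
    first_phase <- cds$phase[ord[1L]]
    total <- sum(cds$end - cds$start + 1L)
    if ((total - first_phase) %% 3L != 0L)
        stop("phase/CDS inconsistency in transcript ", transcript_id,
             ": spliced CDS length ", total, " minus phase ", first_phase,
             " is not a codon multiple")
    list(gene_id = gene_id, transcript_id = transcript_id, chrom = chrom,
         strand = strand, exons = exons, cds = cds)
}

orderCds <- function(cds, strand) {
    if (strand == "+") order(cds$start) else order(-cds$start)
}

#' @rdname transcriptModel
#' @param transcripts list of records from \code{transcriptModel}.
#' @return A \linkS4class{GeneModels} object.
#' @export
geneModels <- function(transcripts) {
    new("GeneModels", transcripts = transcripts)
}

#' Read gene models from GFF3
#'
#' Parses gene / mRNA / exon / CDS features; a transcript without exon
#' features inherits its CDS segments as exons. Phase comes from the GFF3
#' phase column.
#'
#' @param file path to a GFF3 file.
#' @return A \linkS4class{GeneModels} object.
#' @export
readGeneModels <- function(file) {
    gr <- rtracklayer::import(file, format = "gff3")
    typ <- tolower(as.character(gr$type))
    ids <- as.character(gr$ID)
    parents <- vapply(as.list(gr$Parent), function(p)
        if (length(p)) p[[1L]] else NA_character_, character(1))
    mrna <- which(typ %in% c("mrna", "transcript"))
    tx <- lapply(mrna, function(i) {
        tid <- ids[i]
        gid <- parents[i]
        if (is.na(gid)) gid <- tid
        kids <- which(parents == tid)
        ex <- kids[typ[kids] == "exon"]
        cd <- kids[typ[kids] == "cds"]
        exons <- if (length(ex))
            data.frame(start = start(gr)[ex], end = end(gr)[ex])
        else data.frame(start = start(gr)[cd], end = end(gr)[cd])
        phase <- gr$phase[cd]
        if (is.null(phase) || all(is.na(phase))) phase <- rep(0L, length(cd))
        transcriptModel(gid, tid, as.character(seqnames(gr))[i],
                        as.character(strand(gr))[i],
                        exons,
                        data.frame(start = start(gr)[cd],
                                   end = end(gr)[cd],
                                   phase = as.integer(phase)))
    })
    geneModels(tx)
}

translateCodon <- function(codon) {
    if (grepl("[^ACGT]", codon) || nchar(codon) != 3L) return("X")
    unname(GENETIC_CODE[[codon]])
}

complementBase <- function(b) {
    c(A = "T", C = "G", G = "C", T = "A")[[b]]
}

# spliced CDS sequence of a transcript in coding (5'->3') orientation
splicedCds <- function(tx, reference) {
    ord <- orderCds(tx$cds, tx$strand)
    segs <- vapply(ord, function(i)
        refBases(reference, tx$chrom, tx$cds$start[i], tx$cds$end[i]),
        character(1))
    if (tx$strand == "-")
        segs <- vapply(segs, function(s)
            as.character(reverseComplement(DNAString(s))), character(1))
    paste(segs, collapse = "")
}

# genomic position -> 1-based index in the spliced CDS, NA if outside
cdsIndexOf <- function(tx, pos) {
    ord <- orderCds(tx$cds, tx$strand)
    offset <- 0L
    for (i in ord) {
        w <- tx$cds$end[i] - tx$cds$start[i] + 1L
        if (pos >= tx$cds$start[i] && pos <= tx$cds$end[i]) {
            within <- if (tx$strand == "+") pos - tx$cds$start[i] + 1L
                      else tx$cds$end[i] - pos + 1L
            return(offset + within)
        }
        offset <- offset + w
    }
    NA_integer_
}

SEVERITY <- c(frameshift = 9, nonsense = 9, stop_lost = 8, missense = 7,
              inframe_deletion = 6, inframe_insertion = 6, synonymous = 5,
              noncoding_exon = 4, intron = 3, intergenic = 1)

classifySnpInCds <- function(tx, pos, alt, reference) {
    cds_seq <- splicedCds(tx, reference)
    ord <- orderCds(tx$cds, tx$strand)
    phase <- tx$cds$phase[ord[1L]]
    ci <- cdsIndexOf(tx, pos)
    coding_i <- ci - phase
    if (coding_i < 1L)
        return(list(category = NA_character_, codon_change = NA_character_,
                    aa_change = NA_character_))
    codon_idx <- (coding_i - 1L) %/% 3L
    within <- (coding_i - 1L) %% 3L
    ref_codon <- substr(cds_seq, phase + codon_idx * 3L + 1L,
                        phase + codon_idx * 3L + 3L)
    while (nchar(ref_codon) < 3L) ref_codon <- paste0(ref_codon, "N")
    alt_tx <- if (tx$strand == "-") complementBase(alt) else alt
    alt_codon <- ref_codon
    substr(alt_codon, within + 1L, within + 1L) <- alt_tx
    ref_aa <- translateCodon(ref_codon)
    alt_aa <- translateCodon(alt_codon)
    if (ref_aa == "X" || alt_aa == "X")
        return(list(category = NA_character_, codon_change = NA_character_,
                    aa_change = NA_character_))
    category <- if (ref_aa == alt_aa) "synonymous"
        else if (alt_aa == "*") "nonsense"
        else if (ref_aa == "*") "stop_lost"
        else "missense"
    list(category = category,
         codon_change = paste0(ref_codon, ">", alt_codon),
         aa_change = paste0(ref_aa, codon_idx + 1L, alt_aa))
}

# consequence of one allele atom against one transcript
consequenceForTranscript <- function(tx, pos, ref, alt, reference) {
    span_lo <- pos; span_hi <- pos + nchar(ref) - 1L
    is_snp <- nchar(ref) == 1L && nchar(alt) == 1L
    in_cds <- any(span_lo <= tx$cds$end & span_hi >= tx$cds$start)
    if (is_snp) {
        if (in_cds) return(classifySnpInCds(tx, pos, alt, reference))
        in_exon <- any(pos >= tx$exons$start & pos <= tx$exons$end)
        return(list(category = if (in_exon) "noncoding_exon" else "intron",
                    codon_change = NA_character_,
                    aa_change = NA_character_))
    }
    # indel
    if (in_cds) {
        len_diff <- nchar(alt) - nchar(ref)
        if (len_diff %% 3L != 0L)
            return(list(category = "frameshift",
                        codon_change = NA_character_,
                        aa_change = aaPositionLabel(tx, span_lo, span_hi)))
        return(list(category = if (len_diff < 0L) "inframe_deletion"
                               else "inframe_insertion",
                    codon_change = NA_character_,
                    aa_change = aaPositionLabel(tx, span_lo, span_hi)))
    }
    in_exon <- any(span_lo <= tx$exons$end & span_hi >= tx$exons$start)
    list(category = if (in_exon) "noncoding_exon" else "intron",
         codon_change = NA_character_, aa_change = NA_character_)
}

# residue range affected by an indel, e.g. "12-13"
aaPositionLabel <- function(tx, span_lo, span_hi) {
    ord <- orderCds(tx$cds, tx$strand)
    phase <- tx$cds$phase[ord[1L]]
    idx <- c(cdsIndexOf(tx, span_lo), cdsIndexOf(tx, span_hi))
    idx <- idx[!is.na(idx)]
    if (!length(idx)) return(NA_character_)
    aa <- sort(unique(pmax(1L, (idx - phase - 1L) %/% 3L + 1L)))
    if (length(aa) == 1L || aa[1L] == aa[length(aa)])
        as.character(aa[1L])
    else paste0(aa[1L], "-", aa[length(aa)])
}

#' Annotate variants with predicted functional consequences
#'
#' Classifies each variant allele against every overlapping transcript:
#' coding SNPs by codon translation (synonymous, missense, nonsense,
#' stop_lost; reverse-complemented on minus-strand genes, reading frame
#' from CDS phase), coding indels as frameshift when their length change
#' is not a codon multiple and as inframe insertion/deletion otherwise,
#' and non-coding variants as noncoding_exon, intron or intergenic.
#'
#' @param sites a \linkS4class{VariantSites} object.
#' @param models a \linkS4class{GeneModels} object.
#' @param reference named \linkS4class{DNAStringSet}.
#' @return data.frame with one row per (site allele, transcript)
#'   combination (intergenic alleles get a single row): \code{site}
#'   (index into \code{sites}), \code{chrom}, \code{pos}, \code{ref},
#'   \code{alt}, \code{gene_id}, \code{transcript_id}, \code{category},
#'   \code{codon_change}, \code{aa_change}.
#' @export
annotateVariants <- function(sites, models, reference) {
    atoms <- siteAtoms(sites)
    rows <- list()
    for (k in seq_len(nrow(atoms))) {
        pos <- atoms$pos[k]; ref <- atoms$ref[k]; alt <- atoms$alt[k]
        span_hi <- pos + nchar(ref) - 1L
        hit <- FALSE
        for (tx in models@transcripts) {
            if (tx$chrom != atoms$chrom[k]) next
            tx_lo <- min(tx$exons$start); tx_hi <- max(tx$exons$end)
            if (span_hi < tx_lo || pos > tx_hi) next
            hit <- TRUE
            cq <- consequenceForTranscript(tx, pos, ref, alt, reference)
            rows[[length(rows) + 1L]] <- data.frame(
                site = atoms$site[k], chrom = atoms$chrom[k], pos = pos,
                ref = ref, alt = alt, gene_id = tx$gene_id,
                transcript_id = tx$transcript_id,
                category = cq$category, codon_change = cq$codon_change,
                aa_change = cq$aa_change, stringsAsFactors = FALSE)
        }
        if (!hit)
            rows[[length(rows) + 1L]] <- data.frame(
                site = atoms$site[k], chrom = atoms$chrom[k], pos = pos,
                ref = ref, alt = alt, gene_id = NA_character_,
                transcript_id = NA_character_, category = "intergenic",
                codon_change = NA_character_, aa_change = NA_character_,
                stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
}

#' Most severe consequence per site
#'
#' Severity order: frameshift/nonsense, then stop_lost, missense, inframe
#' changes, synonymous, non-coding exon, intron, intergenic.
#'
#' @param annotations result of \code{\link{annotateVariants}}.
#' @return data.frame with one row per annotated site: \code{site},
#'   \code{chrom}, \code{pos}, \code{category}, \code{gene_id}.
#' @export
mostSevereConsequence <- function(annotations) {
    sev <- SEVERITY[annotations$category]
    sev[is.na(sev)] <- 0
    o <- order(annotations$site, -sev)
    a <- annotations[o, , drop = FALSE]
    a <- a[!duplicated(a$site), c("site", "chrom", "pos", "category",
                                  "gene_id")]
    rownames(a) <- NULL
    a
}

#' Per-gene variant counts and SNP density
#'
#' Counts coding variants per gene by most-severe category (per variant,
#' across the gene's transcripts) and computes the SNP density per kbp of
#' covered exonic sequence.
#'
#' @param annotations result of \code{\link{annotateVariants}}.
#' @param covered_exonic_bp named numeric vector: covered exonic bp per
#'   gene_id. Genes annotated but missing here are omitted with a warning.
#' @return data.frame with one row per gene: counts per coding category,
#'   total coding variants, covered bp, and \code{density_per_kbp}
#'   (coding variants x 1000 / covered bp).
#' @export
geneVariantSummary <- function(annotations, covered_exonic_bp) {
    coding <- c("synonymous", "missense", "nonsense", "stop_lost",
                "frameshift", "inframe_deletion", "inframe_insertion")
    ann <- annotations[!is.na(annotations$gene_id), , drop = FALSE]
    # most severe per (site, gene)
    sev <- SEVERITY[ann$category]; sev[is.na(sev)] <- 0
    o <- order(ann$site, ann$gene_id, -sev)
    ann <- ann[o, , drop = FALSE]
    ann <- ann[!duplicated(ann[c("site", "gene_id")]), , drop = FALSE]
    seen <- sort(unique(ann$gene_id))
    known <- seen %in% names(covered_exonic_bp)
    if (any(!known))
        warning("no coverage info for gene(s): ",
                paste(seen[!known], collapse = ", "), "; omitted")
    # covered genes without variants get an all-zero row
    genes <- sort(unique(c(seen[known], names(covered_exonic_bp))))
    out <- lapply(genes, function(g) {
        a <- ann[ann$gene_id == g, , drop = FALSE]
        cnt <- vapply(coding, function(cc) sum(a$category == cc,
                                               na.rm = TRUE), integer(1))
        n_coding <- sum(cnt)
        bp <- covered_exonic_bp[[g]]
        data.frame(gene_id = g, t(cnt), n_coding = n_coding,
                   covered_exonic_bp = bp,
                   density_per_kbp = n_coding * 1000 / bp,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    rownames(out) <- NULL
    out
}

#' Genome-wide SNP density
#'
#' @param n_variants number of variants.
#' @param total_bp total sequence length surveyed.
#' @return base pairs per variant.
#' @examples
#' genomeSnpDensity(32e6, 400e6)  # 12.5 bp per SNP
#' @export
genomeSnpDensity <- function(n_variants, total_bp) {
    if (n_variants <= 0) stop("n_variants must be positive")
    total_bp / n_variants
}
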
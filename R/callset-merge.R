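#' @include AllClasses.R variant-sites.R vcf-io.R
NULL

#' Merge variant callsets from multiple discovery pipelines
#'
#' Takes the set union of normalized sites across pipelines and records,
#' per site, every pipeline that called it. Sites are fused on
#' (chrom, pos, ref): when different pipelines report different
#' alternative alleles at one position the merged site carries all of them
#' and is classified multiallelic, even if each individual caller saw it
#' as biallelic. The union is idempotent and order-independent.
#'
#' @param callsets a named list of \linkS4class{VariantSites} (names are
#'   pipeline ids), or an unnamed list of sites that already carry their
#'   provenance (as produced by \code{\link{readCallset}}).
#' @return A \linkS4class{VariantSites} object with merged provenance,
#'   sorted by genomic position.
#' @examples
#' a <- VariantSites("chr1", c(10L, 20L), c("A", "C"), c("G", "T"))
#' b <- VariantSites("chr1", c(20L, 30L), c("C", "G"), c("T", "A"))
#' m <- mergeCallsets(list(p1 = a, p2 = b))
#' vtypeCounts(m)
#' @export
mergeCallsets <- function(callsets) {
    stopifnot(length(callsets) >= 1L)
    nm <- names(callsets)
    if (!is.null(nm) && any(nzchar(nm)) && anyDuplicated(nm[nzchar(nm)]))
        stop("duplicate pipeline_id in callsets: ",
             paste(unique(nm[duplicated(nm)]), collapse = ", "))
    atom_list <- lapply(seq_along(callsets), function(k) {
        x <- callsets[[k]]
        stopifnot(is(x, "VariantSites"))
        at <- siteAtoms(x)
        prov <- as.list(x@provenance)
        if (!is.null(nm) && nzchar(nm[k]))
            prov <- lapply(prov, function(p) unique(c(p, nm[k])))
        at$pipelines <- prov[at$site]
        at$site <- NULL
        at
    })
    atoms <- do.call(rbind, atom_list)
    if (any(lengths(atoms$pipelines) == 0L))
        stop("unnamed callset without provenance; name the list elements")
    fuseAtoms(atoms)
}

#' Intersection summary of a merged callset
#'
#' @param merged a \linkS4class{VariantSites} with provenance (from
#'   \code{\link{mergeCallsets}}).
#' @return list with \code{per_pipeline} (named site counts),
#'   \code{pairwise} (symmetric matrix of shared-site counts; the diagonal
#'   is the per-pipeline count), \code{exclusive_by_k} (sites called by
#'   exactly k pipelines, a partition of the union) and \code{private}
#'   (per pipeline, sites called by it alone).
#' @export
intersectionSummary <- function(merged) {
    if (!length(merged)) stop("empty provenance")
    prov <- as.list(merged@provenance)
    pipes <- sort(unique(unlist(prov)))
    member <- vapply(pipes, function(p)
        vapply(prov, function(s) p %in% s, logical(1)),
        logical(length(prov)))
    member <- matrix(member, nrow = length(prov),
                     dimnames = list(NULL, pipes))
    pairwise <- crossprod(member)
    k <- rowSums(member)
    exclusive_by_k <- table(factor(k, levels = seq_along(pipes)))
    private <- colSums(member[k == 1L, , drop = FALSE])
    list(per_pipeline = colSums(member),
         pairwise = pairwise,
         exclusive_by_k = stats::setNames(as.integer(exclusive_by_k),
                                          names(exclusive_by_k)),
         private = private)
}

#' Cross-aligner consistency of one variant caller
#'
#' Jaccard agreement between the sites a caller reported from two
#' different read aligners: shared sites over the union of sites called
#' under either aligner.
#'
#' @param merged a \linkS4class{VariantSites} with provenance.
#' @param caller_label caller name (pipeline ids are
#'   \code{"<aligner><sep><caller>"}).
#' @param aligners the two aligner labels (default bowtie2 and bwa).
#' @param sep separator inside pipeline ids (default \code{"_"}).
#' @return fraction in [0, 1].
#' @export
alignerConsistency <- function(merged, caller_label,
                               aligners = c("bowtie2", "bwa"), sep = "_") {
    stopifnot(length(aligners) == 2L)
    roster <- unique(unlist(as.list(merged@provenance)))
    ids <- paste(aligners, caller_label, sep = sep)
    absent <- setdiff(ids, roster)
    if (length(absent))
        stop("caller absent under aligner(s): ",
             paste(absent, collapse = ", "))
    prov <- as.list(merged@provenance)
    in1 <- vapply(prov, function(s) ids[1L] %in% s, logical(1))
    in2 <- vapply(prov, function(s) ids[2L] %in% s, logical(1))
    sum(in1 & in2) / sum(in1 | in2)
}

#' Overlap of a merged callset with an external reference callset
#'
#' Counts merged sites for which at least one (chrom, pos, ref, alt)
#' allele also appears in an external callset normalized the same way,
#' optionally stratified by minor-allele-frequency bin.
#'
#' @param merged a \linkS4class{VariantSites} object.
#' @param external a \linkS4class{VariantSites} object (e.g. a WGS panel).
#' @param maf optional numeric per-site MAF for \code{merged}, used for
#'   stratification.
#' @param bins MAF bin breakpoints (default
#'   \code{c(0, 0.01, 0.05, 0.1, 0.25, 0.5)}).
#' @return list with \code{n_overlap}, \code{fraction}, \code{in_both}
#'   (logical per merged site) and, when \code{maf} is given,
#'   \code{by_bin} (data.frame of totals and overlaps per MAF bin).
#' @export
overlapWithReference <- function(merged, external, maf = NULL,
                                 bins = c(0, 0.01, 0.05, 0.1, 0.25, 0.5)) {
    if (!length(merged))
        return(list(n_overlap = 0L, fraction = NA_real_,
                    in_both = logical(0)))
    ext_keys <- with(siteAtoms(external),
                     paste(chrom, pos, ref, alt, sep = ":"))
    at <- siteAtoms(merged)
    hit_atom <- paste(at$chrom, at$pos, at$ref, at$alt, sep = ":") %in%
        ext_keys
    per_site <- tapply(hit_atom, at$site, any)
    in_both <- unname(per_site[as.character(seq_len(length(merged)))])
    in_both[is.na(in_both)] <- FALSE
    in_both <- as.logical(in_both)
    out <- list(n_overlap = sum(in_both),
                fraction = mean(in_both), in_both = in_both)
    if (!is.null(maf)) {
        bin <- cut(pmin(maf, 0.5), breaks = bins, include.lowest = TRUE)
        out$by_bin <- data.frame(
            bin = levels(bin),
            n_sites = as.integer(table(bin)),
            n_overlap = as.integer(tapply(in_both, bin, sum,
                                          default = 0L)))
        out$by_bin$fraction <- ifelse(out$by_bin$n_sites > 0,
                                      out$by_bin$n_overlap /
                                          out$by_bin$n_sites, NA_real_)
        rownames(out$by_bin) <- NULL
    }
    out
}

#' Write the intersection summary as TSV files
#'
#' @param summary result of \code{\link{intersectionSummary}}.
#' @param prefix output path prefix; writes
#'   \code{<prefix>_per_pipeline.tsv} and \code{<prefix>_pairwise.tsv}.
#' @return invisibly, the written paths.
#' @export
writeIntersectionSummary <- function(summary, prefix) {
    p1 <- paste0(prefix, "_per_pipeline.tsv")
    utils::write.table(
        data.frame(pipeline_id = names(summary$per_pipeline),
                   n_sites = as.integer(summary$per_pipeline),
                   n_private = as.integer(summary$private)),
        p1, sep = "\t", quote = FALSE, row.names = FALSE)
    p2 <- paste0(prefix, "_pairwise.tsv")
    utils::write.table(as.data.frame(summary$pairwise), p2, sep = "\t",
                       quote = FALSE, row.names = TRUE, col.names = NA)
    invisible(c(p1, p2))
}
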
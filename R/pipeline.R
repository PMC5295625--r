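#' @include AllClasses.R regions-qc.R callset-merge.R pool-counts.R
#'   curation-filters.R annotation.R
NULL

#' Read a pipeline run configuration
#'
#' The configuration is a single YAML (key-value) file. Recognised keys:
#' \code{regions_bed}, \code{regions_meta}, \code{fragments_tsv},
#' \code{reference_fasta}, \code{gff3}, \code{counts_tsv},
#' \code{callsets} (mapping pipeline_id to VCF path), \code{bam_files}
#' (mapping pool_id to BAM path), \code{covered_exonic_bp} (TSV with
#' gene_id and covered bp), \code{out_dir}, \code{seed}, \code{pools}
#' (\code{n_samples}, \code{ploidy}) and \code{filter} (any
#' \code{\link{filterConfig}} field). Every referenced input path must
#' exist at validation time.
#'
#' @param file path to the YAML config.
#' @return a named list with a populated \code{filter} element
#'   (\linkS4class{FilterConfig}).
#' @export
readRunConfig <- function(file) {
    cfg <- yaml::read_yaml(file)
    path_keys <- c("regions_bed", "regions_meta", "fragments_tsv",
                   "reference_fasta", "gff3", "counts_tsv",
                   "covered_exonic_bp")
    for (k in path_keys)
        if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]]))
            stop("config path for '", k, "' does not exist: ", cfg[[k]])
    for (grp in c("callsets", "bam_files"))
        for (p in unlist(cfg[[grp]]))
            if (!file.exists(p))
                stop("config path in '", grp, "' does not exist: ", p)
    flt <- if (is.null(cfg$filter)) list() else cfg$filter
    cfg$filter <- do.call(filterConfig,
                          flt[names(flt) %in%
                              methods::slotNames("FilterConfig")])
    if (is.null(cfg$out_dir)) cfg$out_dir <- "."
    if (is.null(cfg$pools)) cfg$pools <- list(n_samples = 200L, ploidy = 2L)
    cfg
}

logThresholds <- function(cfg) {
    f <- cfg$filter
    message("thresholds: min_total_depth=", f@min_total_depth,
            " min_pools_present=", f@min_pools_present,
            " min_alt_reads_presence=", f@min_alt_reads_presence,
            " error_ratio_threshold=", f@error_ratio_threshold,
            " error_ranks=", f@error_rank_lo, "-", f@error_rank_hi,
            " aggregate_mode=", f@aggregate_mode)
}

#' Run the region QC stage
#'
#' Reads the target regions and fragment table from the config, assigns
#' fragments by reciprocal overlap, and writes the per-region per-pool
#' depth table (\code{depth_table.tsv}) plus a QC report
#' (\code{qc_report.tsv}: capture rate and flagged low-coverage
#' region/pool pairs).
#'
#' @param cfg config list from \code{\link{readRunConfig}}.
#' @return list with \code{capture_rate}, \code{depth}, \code{flags}.
#' @export
runQc <- function(cfg) {
    if (is.null(cfg$regions_bed)) stop("qc stage: 'regions_bed' missing")
    if (is.null(cfg$fragments_tsv))
        stop("qc stage: 'fragments_tsv' missing")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    regions <- readTargetRegions(cfg$regions_bed, cfg$regions_meta)
    frags <- readFragments(cfg$fragments_tsv)
    rate <- captureRate(frags, regions)
    dt <- regionDepthTable(frags, regions)
    utils::write.table(
        data.frame(region_id = rownames(dt$depth), dt$depth,
                   check.names = FALSE),
        file.path(cfg$out_dir, "depth_table.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    rep_file <- file.path(cfg$out_dir, "qc_report.tsv")
    writeLines(c(paste0("# capture_rate\t", format(rate, digits = 6)),
                 paste(c("region_id", "pool_id", "count"),
                       collapse = "\t"),
                 if (nrow(dt$flags))
                     paste(dt$flags$region_id, dt$flags$pool_id,
                           dt$flags$count, sep = "\t")),
               rep_file)
    message("qc: capture rate ", format(rate, digits = 4), "; ",
            nrow(dt$flags), " low-coverage region/pool pair(s)")
    list(capture_rate = rate, depth = dt$depth, flags = dt$flags)
}

#' Run the merge + curation stage
#'
#' Reads every discovery pipeline's VCF, merges them into a provenance-
#' tracked union, obtains pooled allele counts (from a counts TSV or by
#' pileup over per-pool BAMs), applies the filter cascade and writes:
#' \code{merged.vcf}, \code{curated.vcf}, \code{curated_table.tsv},
#' \code{filter_report.tsv}, the intersection summary TSVs and the
#' cross-pool frequency-consistency table.
#'
#' @param cfg config list from \code{\link{readRunConfig}}.
#' @return list with \code{merged}, \code{curated} (result of
#'   \code{\link{applyCascade}}), \code{summary} and \code{consistency}.
#' @export
runCuration <- function(cfg) {
    if (is.null(cfg$callsets) || !length(cfg$callsets))
        stop("curation stage: 'callsets' missing")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    logThresholds(cfg)
    reference <- if (!is.null(cfg$reference_fasta))
        readReference(cfg$reference_fasta)
    callsets <- lapply(names(cfg$callsets), function(pid)
        readCallset(cfg$callsets[[pid]], pid, reference))
    names(callsets) <- names(cfg$callsets)
    merged <- mergeCallsets(callsets)
    writeSitesVcf(merged, file.path(cfg$out_dir, "merged.vcf"))
    counts <- if (!is.null(cfg$counts_tsv))
        readPoolCounts(cfg$counts_tsv,
                       n_samples = cfg$pools$n_samples,
                       ploidy = cfg$pools$ploidy)
    else if (!is.null(cfg$bam_files))
        countAlleles(unlist(cfg$bam_files), merged,
                     n_samples = cfg$pools$n_samples,
                     ploidy = cfg$pools$ploidy)
    else stop("curation stage: need 'counts_tsv' or 'bam_files'")
    curated <- applyCascade(merged, counts, cfg$filter)
    writeSitesVcf(curated$sites, file.path(cfg$out_dir, "curated.vcf"),
                  pool_freqs = curated$frequencies,
                  pool_counts = curated$counts)
    writeCuratedTable(curated, file.path(cfg$out_dir,
                                         "curated_table.tsv"))
    writeFilterReport(curated$report,
                      file.path(cfg$out_dir, "filter_report.tsv"))
    summary <- if (length(merged)) intersectionSummary(merged)
    if (!is.null(summary))
        writeIntersectionSummary(summary,
                                 file.path(cfg$out_dir, "intersections"))
    consistency <- poolFrequencyRanges(curated$counts)
    utils::write.table(consistency,
                       file.path(cfg$out_dir, "freq_consistency.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    message("curation: ", length(merged), " merged sites -> ",
            length(curated$sites), " curated SNPs")
    list(merged = merged, curated = curated, summary = summary,
         consistency = consistency)
}

#' Run the functional annotation stage
#'
#' Annotates the curated VCF (or any VCF named by \code{cfg$annotate_vcf})
#' against the gene models and writes \code{annotations.tsv} plus, when
#' per-gene covered exonic lengths are available, \code{gene_summary.tsv}.
#'
#' @param cfg config list from \code{\link{readRunConfig}}.
#' @return list with \code{annotations} and \code{gene_summary}
#'   (\code{NULL} when no coverage info is configured).
#' @export
runAnnotation <- function(cfg) {
    if (is.null(cfg$gff3)) stop("annotation stage: 'gff3' missing")
    if (is.null(cfg$reference_fasta))
        stop("annotation stage: 'reference_fasta' missing")
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    vcf <- if (!is.null(cfg$annotate_vcf)) cfg$annotate_vcf
           else file.path(cfg$out_dir, "curated.vcf")
    if (!file.exists(vcf))
        stop("annotation stage: no VCF to annotate at ", vcf)
    reference <- readReference(cfg$reference_fasta)
    sites <- readCallset(vcf, "curated", reference)
    models <- readGeneModels(cfg$gff3)
    ann <- annotateVariants(sites, models, reference)
    utils::write.table(ann, file.path(cfg$out_dir, "annotations.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    gene_summary <- NULL
    if (!is.null(cfg$covered_exonic_bp)) {
        cov <- utils::read.delim(cfg$covered_exonic_bp,
                                 stringsAsFactors = FALSE)
        covered <- stats::setNames(cov$covered_exonic_bp, cov$gene_id)
        gene_summary <- geneVariantSummary(ann, covered)
        utils::write.table(gene_summary,
                           file.path(cfg$out_dir, "gene_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
    }
    message("annotation: ", length(sites), " site(s) against ",
            length(models), " transcript(s)")
    list(annotations = ann, gene_summary = gene_summary)
}

#' Covered exonic length per gene
#'
#' Total CDS length per gene, optionally intersected with the target
#' regions to reflect only the sequenced portion.
#'
#' @param models a \linkS4class{GeneModels} object.
#' @param regions optional \linkS4class{TargetRegions}.
#' @return named numeric vector of bp per gene_id.
#' @export
coveredExonicBp <- function(models, regions = NULL) {
    per_gene <- list()
    for (tx in models@transcripts) {
        gr <- GenomicRanges::reduce(GRanges(tx$chrom,
                                            IRanges(tx$cds$start,
                                                    tx$cds$end)))
        prev <- per_gene[[tx$gene_id]]
        per_gene[[tx$gene_id]] <-
            if (is.null(prev)) gr else GenomicRanges::reduce(c(prev, gr))
    }
    vapply(per_gene, function(gr) {
        if (!is.null(regions))
            gr <- GenomicRanges::intersect(gr, granges(regions))
        sum(width(gr))
    }, numeric(1))
}
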
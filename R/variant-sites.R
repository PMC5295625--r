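#' @include AllClasses.R
NULL

#' @describeIn VariantSites-class number of sites.
#' @param x a VariantSites object.
#' @export
setMethod("length", "VariantSites", function(x) length(x@chrom))

#' @describeIn VariantSites-class subset sites.
#' @param i index vector.
#' @param j,drop,... ignored.
#' @export
setMethod("[", "VariantSites", function(x, i, j, ..., drop = TRUE) {
    new("VariantSites", chrom = x@chrom[i], pos = x@pos[i], ref = x@ref[i],
        alt = x@alt[i], provenance = x@provenance[i])
})

setMethod("show", "VariantSites", function(object) {
    n <- length(object)
    tab <- table(factor(vtype(object),
                        levels = c("biallelic_SNP", "biallelic_indel",
                                   "multiallelic")))
    cat("VariantSites with", n, "sites:",
        tab[["biallelic_SNP"]], "biallelic SNPs,",
        tab[["biallelic_indel"]], "biallelic indels,",
        tab[["multiallelic"]], "multiallelic\n")
    if (n) {
        head_n <- min(n, 5L)
        df <- as.data.frame(object[seq_len(head_n)])
        print(df)
        if (n > head_n) cat("...", n - head_n, "more sites\n")
    }
})

#' Accessors for VariantSites
#'
#' \code{siteChrom}, \code{sitePos}, \code{siteRef} and \code{siteAlt}
#' return the per-site fields; \code{provenance} the per-site set of
#' pipeline ids; \code{vtype} the variant-type classification of each site
#' (\code{biallelic_SNP}, \code{biallelic_indel} or \code{multiallelic}).
#'
#' @param x a \linkS4class{VariantSites} object.
#' @return vectors parallel to the sites.
#' @name VariantSites-accessors
NULL

#' @rdname VariantSites-accessors
#' @export
siteChrom <- function(x) x@chrom

#' @rdname VariantSites-accessors
#' @export
sitePos <- function(x) x@pos

#' @rdname VariantSites-accessors
#' @export
siteRef <- function(x) x@ref

#' @rdname VariantSites-accessors
#' @export
siteAlt <- function(x) x@alt

#' @rdname VariantSites-accessors
#' @export
provenance <- function(x) x@provenance

#' @rdname VariantSites-accessors
#' @export
vtype <- function(x) {
    nalts <- lengths(x@alt)
    first_alt <- vapply(x@alt, function(a) if (length(a)) a[[1L]] else "",
                        character(1))
    ifelse(nalts > 1L, "multiallelic",
           ifelse(nchar(x@ref) == 1L & nchar(first_alt) == 1L,
                  "biallelic_SNP", "biallelic_indel"))
}

#' Classification counts of a merged callset
#'
#' Counts biallelic SNPs, biallelic indels and multiallelic sites; the
#' three classes partition the site set.
#'
#' @param x a \linkS4class{VariantSites} object.
#' @return named integer vector of length 3.
#' @export
vtypeCounts <- function(x) {
    tab <- table(factor(vtype(x), levels = c("biallelic_SNP",
                                             "biallelic_indel",
                                             "multiallelic")))
    stats::setNames(as.integer(tab), names(tab))
}

#' @describeIn VariantSites-class coerce to data.frame (alt and provenance
#'   comma-joined).
#' @param row.names,optional passed on conventionally, unused.
#' @export
setMethod("as.data.frame", "VariantSites",
          function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(chrom = x@chrom, pos = x@pos, ref = x@ref,
               alt = vapply(x@alt, paste, character(1), collapse = ","),
               vtype = vtype(x),
               pipelines = vapply(x@provenance, paste, character(1),
                                  collapse = ","),
               stringsAsFactors = FALSE)
})

# canonical site identity: chrom:pos:ref with sorted alts
siteKeys <- function(x, with_alt = TRUE) {
    if (with_alt) {
        alts <- vapply(x@alt, function(a) paste(sort(a), collapse = ","),
                       character(1))
        paste(x@chrom, x@pos, x@ref, alts, sep = ":")
    } else {
        paste(x@chrom, x@pos, x@ref, sep = ":")
    }
}

# per-allele atoms: one row per (chrom,pos,ref,alt)
siteAtoms <- function(x) {
    n <- lengths(x@alt)
    data.frame(chrom = rep(x@chrom, n), pos = rep(x@pos, n),
               ref = rep(x@ref, n), alt = unlist(x@alt, use.names = FALSE),
               site = rep(seq_along(x@chrom), n), stringsAsFactors = FALSE)
}

#' Sort sites by genomic position
#'
#' @param x a \linkS4class{VariantSites} object.
#' @param decreasing ignored (kept for generic compatibility).
#' @param ... ignored.
#' @return the sites ordered by (chrom, pos, ref).
#' @export
setMethod("sort", "VariantSites", function(x, decreasing = FALSE, ...) {
    x[order(x@chrom, x@pos, x@ref)]
})
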
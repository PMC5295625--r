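# builds a PoolCounts over given per-pool ACGT count arrays
countsFixture <- function(sites, per_pool) {
    pool_ids <- names(per_pool)
    grab <- function(b) sapply(per_pool, function(m) m[, b])
    poolCounts(sites, pool_ids,
               A = matrix(grab("A"), length(sites)),
               C = matrix(grab("C"), length(sites)),
               G = matrix(grab("G"), length(sites)),
               T = matrix(grab("T"), length(sites)))
}

test_that("the error estimate averages the two smallest nucleotide counts", {
    expect_equal(estimateErrors(c(A = 13028, T = 13, C = 9, G = 6)), 7.5)
    expect_equal(estimateErrors(c(A = 100, G = 50, C = 0, T = 0)), 0)
    expect_equal(estimateErrors(c(A = 10, C = 10, G = 10, T = 10)), 10)
    expect_error(estimateErrors(c(ref = 10, alt = 5)), "4 allele")
})

test_that("the error ratio compares the second-ranked allele to the error estimate", {
    expect_equal(errorRatio(c(A = 13028, T = 13, C = 9, G = 6)), 13 / 7.5)
    expect_lt(errorRatio(c(A = 13028, T = 13, C = 9, G = 6)), 5)
    expect_identical(errorRatio(c(A = 100, G = 50, C = 0, T = 0)), Inf)
    expect_identical(errorRatio(c(A = 100, G = 0, C = 0, T = 0)), 0)
    # boundary: 37 / 7.5 = 4.93 is filtered at threshold 5
    expect_equal(errorRatio(c(A = 100, G = 37, C = 5, T = 10)), 37 / 7.5)
    expect_lt(errorRatio(c(A = 100, G = 37, C = 5, T = 10)), 5)
    # ties in counts are resolved by alphabetical allele order,
    # deterministically
    expect_equal(errorRatio(c(A = 50, C = 50, G = 50, T = 50)), 1)
})

test_that("SNPs embedded in indel reference spans are removed", {
    sites <- VariantSites(
        "chr1", c(100L, 105L, 111L, 300L),
        c(strrep("T", 11), "A", "C", "G"),
        IRanges::CharacterList("T", "G", "T", "A"))
    res <- removeEmbeddedInIndels(sites)
    # SNP at 105 lies inside the 100-110 deletion span; 111 is adjacent
    expect_identical(res$removed, c(FALSE, TRUE, FALSE, FALSE))
    expect_identical(length(res$sites), 3L)
    # random fixture against a brute-force containment scan
    set.seed(21)
    refstr <- randomDna(3000)
    ipos <- sort(sample(2500, 12))
    ilen <- sample(2:12, 12, replace = TRUE)
    spos <- sort(sample(2500, 80))
    spos <- setdiff(spos, ipos)
    chrom <- "chr1"
    iref <- substring(refstr, ipos, ipos + ilen - 1L)
    sref <- substring(refstr, spos, spos)
    sites <- VariantSites(
        chrom, c(ipos, spos), c(iref, sref),
        c(substring(iref, 1L, 1L),
          unname(vapply(sref, function(b)
              setdiff(c("A", "C", "G", "T"), b)[1L], character(1)))))
    res <- removeEmbeddedInIndels(sites)
    brute <- vapply(seq_along(sites), function(i) {
        if (vtype(sites)[i] != "biallelic_SNP") return(FALSE)
        p <- sitePos(sites)[i]
        any(p >= ipos & p <= ipos + ilen - 1L)
    }, logical(1))
    expect_identical(res$removed, brute)
})

test_that("the cascade filters in order and reports exact attrition", {
    # empty input
    empty <- VariantSites(character(0), integer(0), character(0),
                          IRanges::CharacterList())
    pc0 <- poolCounts(empty, "p1", A = matrix(0L, 0, 1),
                      C = matrix(0L, 0, 1), G = matrix(0L, 0, 1),
                      T = matrix(0L, 0, 1))
    res <- applyCascade(empty, pc0)
    expect_identical(length(res$sites), 0L)
    expect_true(all(res$report$sites_in == 0L))
    expect_true(all(res$report$sites_out ==
                    res$report$sites_in - res$report$sites_removed))

    # five planted sites, each designed to fall at one stage
    sites <- VariantSites(
        "chr1",
        c(100L, 104L, 200L, 300L, 400L, 500L),
        c("CCCCCCCCCC", "C", "A", "A", "A", "A"),
        IRanges::CharacterList("C", "A", c("G", "T"), "G", "G", "G"))
    # site 1: the indel; site 2: SNP embedded in its span
    # site 3: multiallelic; site 4: total depth 9999 (boundary)
    # site 5: alt present in one pool only; site 6: survives
    mk <- function(a, c, g, t) c(A = a, C = c, G = g, T = t)
    p1 <- rbind(mk(0, 0, 0, 0),        # indel row (ignored for ACGT)
                mk(100, 5000, 0, 0),
                mk(5000, 0, 400, 300),
                mk(4000, 0, 999, 0),
                mk(9000, 0, 3000, 0),
                mk(9000, 2, 3000, 1))
    p2 <- rbind(mk(0, 0, 0, 0),
                mk(100, 5000, 0, 0),
                mk(5000, 0, 400, 300),
                mk(4000, 0, 1000, 0),
                mk(12000, 0, 0, 0),
                mk(9000, 1, 3000, 2))
    pc <- countsFixture(sites, list(p1 = p1, p2 = p2))
    res <- applyCascade(sites, pc, filterConfig())
    expect_identical(res$report$filter,
                     c("embedded_in_indel", "biallelic_snp", "min_depth",
                       "min_pools", "error_ratio"))
    expect_identical(res$report$sites_removed, c(1L, 2L, 1L, 1L, 0L))
    expect_identical(length(res$sites), 1L)
    expect_identical(sitePos(res$sites), 500L)
    # survivors carry adjusted frequencies
    expect_equal(unname(res$frequencies[1, "p1"]), 3000 / 12000)
    # a site with no counts is an error naming it
    orphan <- VariantSites("chr1", 999L, "A", "G")
    expect_error(applyCascade(orphan, pc), "chr1:999")
})

test_that("the cascade is idempotent and monotone in its thresholds", {
    sim <- simulatePools(simConfig(n_sites = 300, n_pools = 4,
                                   depth_per_pool = 4000L,
                                   base_error_rate = 0.003, seed = 31))
    res <- applyCascade(sim$sites, sim$counts,
                        filterConfig(min_total_depth = 8000))
    # idempotence: re-applying to the curated subset removes nothing
    again <- applyCascade(res$sites, res$counts,
                          filterConfig(min_total_depth = 8000))
    expect_identical(length(again$sites), length(res$sites))
    expect_true(all(again$kept))
    # output is a subset of input
    key <- function(x) paste(siteChrom(x), sitePos(x), siteRef(x))
    expect_true(all(key(res$sites) %in% key(sim$sites)))
    # monotonicity: tightening any threshold never grows the curated set
    base_n <- length(res$sites)
    for (cfg in list(filterConfig(min_total_depth = 16000),
                     filterConfig(min_total_depth = 8000,
                                  min_pools_present = 4L),
                     filterConfig(min_total_depth = 8000,
                                  error_ratio_threshold = 50))) {
        expect_lte(length(applyCascade(sim$sites, sim$counts,
                                       cfg)$sites), base_n)
    }
})

test_that("the error-ratio filter separates true rare alleles from base errors", {
    # pure-error sites: no variant, substitution errors only
    null_cfg <- simConfig(n_sites = 400, n_pools = 1,
                          depth_per_pool = 20000L,
                          fixed_pool_fraction = 0,
                          base_error_rate = 0.005, seed = 41)
    null_sim <- simulatePools(null_cfg)
    ratios <- vapply(seq_len(400), function(i)
        errorRatio(poolAlleleCounts(null_sim$counts, i, 1)), numeric(1))
    specificity <- mean(ratios < 5)
    expect_gte(specificity, 0.95)
    # planted rare variants at MAF 0.01, same depth and error rate
    alt_cfg <- simConfig(n_sites = 400, n_pools = 1,
                         depth_per_pool = 20000L,
                         fixed_pool_fraction = 0.01,
                         base_error_rate = 0.005, seed = 42)
    alt_sim <- simulatePools(alt_cfg)
    ratios <- vapply(seq_len(400), function(i)
        errorRatio(poolAlleleCounts(alt_sim$counts, i, 1)), numeric(1))
    sensitivity <- mean(ratios >= 5)
    expect_gte(sensitivity, 0.95)
})
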
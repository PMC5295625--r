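test_that("reciprocal-overlap assignment handles identity, threshold and ties", {
    tr <- TargetRegions(c("r1", "r2"), "chr1", c(101L, 1001L),
                        c(700L, 1600L))
    # identity
    fr <- alignedFragments("chr1", 101, 700, "p1")
    expect_identical(assignFragments(fr, tr), "r1")
    # 50% coverage of the region fails
    fr <- alignedFragments("chr1", 101, 400, "p1")
    expect_identical(assignFragments(fr, tr), NA_character_)
    # exactly 90% both ways is inclusive: frag 600 bp, region 600 bp,
    # overlap 540 bp
    fr <- alignedFragments("chr1", 161, 760, "p1")
    expect_identical(assignFragments(fr, tr), "r1")
    # 539 bp overlap fails
    fr <- alignedFragments("chr1", 162, 761, "p1")
    expect_identical(assignFragments(fr, tr), NA_character_)
    # improper pair and multimapper are never assigned
    fr <- alignedFragments("chr1", c(101, 101), 700, "p1",
                           proper_pair = c(FALSE, TRUE),
                           unique = c(TRUE, FALSE))
    expect_identical(assignFragments(fr, tr),
                     c(NA_character_, NA_character_))
    # fragment on a chromosome with no regions: unassigned, not an error
    fr <- alignedFragments("chr9", 101, 700, "p1")
    expect_identical(assignFragments(fr, tr), NA_character_)
    # exact tie between two identical overlapping regions -> none
    tr2 <- TargetRegions(c("a", "b"), "chr1", c(101L, 101L),
                         c(700L, 700L))
    fr <- alignedFragments("chr1", 101, 700, "p1")
    expect_identical(assignFragments(fr, tr2), NA_character_)
    # malformed interval rejected with message
    expect_error(alignedFragments("chr1", 700, 101, "p1"), "malformed")
})

test_that("capture rate counts assignable fragments over all fragments", {
    tr <- TargetRegions("r1", "chr1", 101L, 700L)
    all_on <- alignedFragments("chr1", rep(101, 4), rep(700, 4), "p1")
    expect_equal(captureRate(all_on, tr), 1.0)
    all_off <- alignedFragments("chr2", rep(101, 4), rep(700, 4), "p1")
    expect_equal(captureRate(all_off, tr), 0.0)
    # 9 of 10 pass: one fragment covers only half its region
    fr <- alignedFragments("chr1", c(rep(101, 9), 101),
                           c(rep(700, 9), 400), "p1")
    expect_equal(captureRate(fr, tr), 0.9)
    expect_error(captureRate(alignedFragments(character(0), integer(0),
                                              integer(0), character(0)),
                             tr), "no fragments")
})

test_that("assignment agrees with the brute-force all-pairs scan", {
    set.seed(42)
    for (rep in 1:3) {
        nr <- sample(10:50, 1)
        starts <- sort(sample(seq(1, 40000, by = 50), nr))
        tr <- TargetRegions(sprintf("r%02d", seq_len(nr)), "chr1", starts,
                            starts + sample(300:700, nr, replace = TRUE))
        nf <- 400
        ridx <- sample(nr, nf, replace = TRUE)
        jit <- sample(-400:400, nf, replace = TRUE)
        fs <- pmax(1L, GenomicRanges::start(tr)[ridx] + jit)
        fe <- fs + sample(250:750, nf, replace = TRUE)
        fr <- alignedFragments("chr1", fs, fe, "p1",
                               proper_pair = runif(nf) > 0.05,
                               unique = runif(nf) > 0.05,
                               max_frag_len = 800L)
        expect_identical(assignFragments(fr, tr), bruteAssign(fr, tr))
    }
})

test_that("capture rate is permutation invariant and region shrinking never raises it", {
    set.seed(7)
    cfg <- simConfig(n_sites = 10, n_regions = 20, seed = 7)
    tr <- simulateRegions(cfg)
    fr <- simulateFragments(cfg, tr, on_target_fraction = 0.8,
                            n_fragments = 300L)
    r0 <- captureRate(fr, tr)
    perm <- sample(length(fr))
    expect_equal(captureRate(fr[perm], tr), r0)
    shrunk <- TargetRegions(S4Vectors::mcols(tr)$region_id,
                            as.character(GenomicRanges::seqnames(tr)),
                            GenomicRanges::start(tr),
                            GenomicRanges::start(tr) +
                                GenomicRanges::width(tr) %/% 2L - 1L)
    expect_lte(captureRate(fr, shrunk), r0)
})

test_that("depth table is complete with zeros and flags strictly below threshold", {
    tr <- TargetRegions(c("r1", "r2"), "chr1", c(101L, 1001L),
                        c(700L, 1600L))
    # r1: 20 fragments in p1, 19 in p2; r2: none anywhere
    fr <- alignedFragments("chr1", rep(101, 39), rep(700, 39),
                           c(rep("p1", 20), rep("p2", 19)))
    dt <- regionDepthTable(fr, tr)
    expect_identical(dim(dt$depth), c(2L, 2L))
    expect_identical(dt$depth["r1", "p1"], 20L)
    expect_identical(dt$depth["r2", "p1"], 0L)
    # 20 is not flagged (boundary is strict less-than); 19 is; r2 in both
    expect_identical(nrow(dt$flags), 3L)
    expect_false(any(dt$flags$region_id == "r1" & dt$flags$pool_id == "p1"))
    expect_true(any(dt$flags$region_id == "r1" & dt$flags$pool_id == "p2"))
    expect_identical(sum(dt$flags$region_id == "r2"), 2L)
    expect_false(is.unsorted(dt$flags$region_id))
})

test_that("expected depth and trim coverage gap follow the design arithmetic", {
    expect_equal(round(expectedDepth(2500000, 121)), 20661)
    expect_equal(signif(expectedDepth(2500000, 121), 1), 20000)
    expect_equal(expectedDepth(0, 121), 0)
    expect_equal(expectedDepth(1000, 10), 100)
    expect_error(expectedDepth(1000, 0), "positive")
    expect_equal(coverageGap(600, 240, 170), 190)
    expect_equal(coverageGap(400, 240, 170), 0)
    expect_equal(coverageGap(410, 240, 170), 0)
})

test_that("region BED + sidecar and fragment TSV round-trip", {
    tr <- TargetRegions(c("r1", "r2"), "chr1", c(101L, 1001L),
                        c(700L, 1600L), primer_pair = c("pA", "pB"),
                        expected_amplicon_len = c(600L, 600L))
    bed <- tempfile(fileext = ".bed"); meta <- tempfile(fileext = ".tsv")
    writeTargetRegions(tr, bed, meta)
    tr2 <- readTargetRegions(bed, meta)
    expect_identical(GenomicRanges::start(tr2), GenomicRanges::start(tr))
    expect_identical(GenomicRanges::end(tr2), GenomicRanges::end(tr))
    expect_identical(S4Vectors::mcols(tr2)$primer_pair, c("pA", "pB"))
    fr <- alignedFragments("chr1", c(101, 1001), c(700, 1600),
                           c("p1", "p2"), c(TRUE, FALSE), c(TRUE, TRUE))
    tsv <- tempfile(fileext = ".tsv")
    writeFragments(fr, tsv)
    fr2 <- readFragments(tsv)
    expect_identical(GenomicRanges::start(fr2), GenomicRanges::start(fr))
    expect_identical(S4Vectors::mcols(fr2)$proper_pair, c(TRUE, FALSE))
})

test_that("fragments are derived from paired SAM records", {
    sam <- tempfile(fileext = ".sam")
    lines <- c("@HD\tVN:1.6\tSO:coordinate",
               "@SQ\tSN:chr1\tLN:2000",
               paste("q1", "99", "chr1", "101", "60", "100M", "=", "601",
                     "600", strrep("A", 100), strrep("I", 100), sep = "\t"),
               paste("q1", "147", "chr1", "601", "60", "100M", "=", "101",
                     "-600", strrep("A", 100), strrep("I", 100), sep = "\t"))
    writeLines(lines, sam)
    fr <- fragmentsFromBam(sam, "p1")
    expect_identical(length(fr), 1L)
    expect_identical(GenomicRanges::start(fr), 101L)
    expect_identical(GenomicRanges::end(fr), 700L)
    expect_true(S4Vectors::mcols(fr)$proper_pair)
    expect_true(S4Vectors::mcols(fr)$unique)
})
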
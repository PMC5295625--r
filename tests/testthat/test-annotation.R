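test_that("coding SNPs are classified by codon translation", {
    # + strand gene with CDS ATG GGA TGG TGG TGA at 11-25
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("A", 10), "ATGGGATGGTGGTGA", strrep("C", 10))))
    gm <- geneModels(list(toyGene("g1", "chr1", 11L, 15L)))
    cases <- data.frame(
        pos = c(16L, 22L, 15L, 24L, 3L),
        refb = c("A", "G", "G", "G", "A"),
        altb = c("G", "A", "T", "C", "C"),
        want = c("synonymous",   # GGA>GGG, Gly>Gly
                 "nonsense",     # TGG>TGA, Trp>stop
                 "missense",     # GGA>GTA, Gly>Val
                 "stop_lost",    # TGA>TCA, stop>Ser
                 "intergenic"))
    for (i in seq_len(nrow(cases))) {
        vs <- VariantSites("chr1", cases$pos[i], cases$refb[i],
                           cases$altb[i])
        ann <- annotateVariants(vs, gm, ref)
        expect_identical(ann$category, cases$want[i])
    }
})

test_that("codon translation agrees with the Biostrings translator on all 64 codons", {
    bases <- c("A", "C", "G", "T")
    codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
    for (cod in codons) {
        mine <- ampliPool:::translateCodon(cod)
        oracle <- as.character(Biostrings::translate(
            Biostrings::DNAString(cod), no.init.codon = TRUE))
        expect_identical(mine, oracle)
    }
})

test_that("a 1 bp CDS deletion on a minus-strand gene is a frameshift", {
    # minus-strand CDS: genomic 11-22 reverse-complements to the ORF
    orf <- "ATGGCCAAATGA"
    rc <- as.character(Biostrings::reverseComplement(
        Biostrings::DNAString(orf)))
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("T", 10), rc, strrep("T", 10))))
    gm <- geneModels(list(toyGene("g1", "chr1", 11L, 12L,
                                  strand = "-")))
    # hand-check: the reference really translates to Met-Ala-Lys-stop
    expect_identical(as.character(Biostrings::translate(
        Biostrings::DNAString(orf))), "MAK*")
    # 1 bp deletion inside the CDS
    refa <- substr(rc, 4, 5)
    vs <- VariantSites("chr1", 14L, refa, substr(refa, 1, 1))
    ann <- annotateVariants(vs, gm, ref)
    expect_identical(ann$category, "frameshift")
    # 3 bp deletion is inframe
    refa <- substr(rc, 4, 7)
    vs <- VariantSites("chr1", 14L, refa, substr(refa, 1, 1))
    ann <- annotateVariants(vs, gm, ref)
    expect_identical(ann$category, "inframe_deletion")
    # minus-strand SNP: mutate the genomic base pairing with the ORF's
    # 2nd codon so that Ala becomes Val (GCC -> GTC)
    # ORF index 5 (C) maps to genomic pos 22 - 5 + 1 = 18, base G
    vs <- VariantSites("chr1", 18L, "G", "A")
    ann <- annotateVariants(vs, gm, ref)
    expect_identical(ann$category, "missense")
    expect_identical(ann$aa_change, "A2V")
})

test_that("mirrored plus and minus strand genes give identical categories", {
    set.seed(17)
    for (rep in 1:5) {
        n_codons <- sample(4:10, 1)
        orf <- paste0("ATG",
                      paste(sample(c("GGA", "GCC", "AAA", "TTC", "CTG",
                                     "TGG", "GAT"), n_codons - 2,
                                   replace = TRUE), collapse = ""),
                      "TGA")
        L <- nchar(orf)
        pad <- 10L
        fwd_ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
            strrep("A", pad), orf, strrep("A", pad))))
        rc <- as.character(Biostrings::reverseComplement(
            Biostrings::DNAString(orf)))
        rev_ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
            strrep("T", pad), rc, strrep("T", pad))))
        gm_fwd <- geneModels(list(toyGene("g", "chr1", pad + 1L, L)))
        gm_rev <- geneModels(list(toyGene("g", "chr1", pad + 1L, L,
                                          strand = "-")))
        for (k in 1:8) {
            i <- sample(L, 1)                     # ORF coordinate
            fwd_pos <- pad + i
            rev_pos <- pad + L - i + 1L
            b <- substr(orf, i, i)
            alt <- sample(setdiff(c("A", "C", "G", "T"), b), 1)
            comp <- c(A = "T", C = "G", G = "C", T = "A")
            a_f <- annotateVariants(
                VariantSites("chr1", fwd_pos, b, alt), gm_fwd, fwd_ref)
            a_r <- annotateVariants(
                VariantSites("chr1", rev_pos, comp[[b]], comp[[alt]]),
                gm_rev, rev_ref)
            expect_identical(a_f$category, a_r$category)
            expect_identical(a_f$aa_change, a_r$aa_change)
        }
    }
})

test_that("every CDS SNP gets exactly one coding category per transcript", {
    set.seed(23)
    orf <- paste0("ATG", paste(sample(c("GGA", "GCC", "AAA", "TTC"),
                                      10, replace = TRUE),
                               collapse = ""), "TGA")
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("A", 10), orf, strrep("A", 10))))
    gm <- geneModels(list(toyGene("g1", "chr1", 11L, nchar(orf))))
    coding <- c("synonymous", "missense", "nonsense", "stop_lost")
    for (pos in 11:(10 + nchar(orf))) {
        b <- substr(orf, pos - 10L, pos - 10L)
        alt <- setdiff(c("A", "C", "G", "T"), b)[1L]
        ann <- annotateVariants(VariantSites("chr1", pos, b, alt),
                                gm, ref)
        expect_identical(nrow(ann), 1L)
        expect_identical(sum(ann$category %in% coding), 1L)
    }
})

test_that("intron, non-coding exon and multi-transcript models are handled", {
    # gene with two exons 11-22 and 31-42; CDS only 11-22
    tx1 <- transcriptModel("g1", "t1", "chr1", "+",
                           exons = data.frame(start = c(11L, 31L),
                                              end = c(22L, 42L)),
                           cds = data.frame(start = 11L, end = 22L,
                                            phase = 0L))
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("A", 10), "ATGGCCAAATGA", strrep("C", 8),
        "GGGGGGGGGGGG", strrep("A", 10))))
    gm <- geneModels(list(tx1))
    ann <- annotateVariants(VariantSites("chr1", 25L, "C", "G"), gm, ref)
    expect_identical(ann$category, "intron")
    ann <- annotateVariants(VariantSites("chr1", 35L, "G", "A"), gm, ref)
    expect_identical(ann$category, "noncoding_exon")
    # phase/CDS inconsistency errors with the transcript name
    expect_error(transcriptModel("g2", "bad_tx", "chr1", "+",
                                 exons = data.frame(start = 1L, end = 10L),
                                 cds = data.frame(start = 1L, end = 10L,
                                                  phase = 0L)),
                 "bad_tx")
})

test_that("GFF3 round-trip drives annotation", {
    gff <- tempfile(fileext = ".gff3")
    writeLines(c(
        "##gff-version 3",
        "chr1\ttest\tgene\t11\t25\t.\t+\t.\tID=g1",
        "chr1\ttest\tmRNA\t11\t25\t.\t+\t.\tID=t1;Parent=g1",
        "chr1\ttest\texon\t11\t25\t.\t+\t.\tID=e1;Parent=t1",
        "chr1\ttest\tCDS\t11\t25\t.\t+\t0\tID=c1;Parent=t1"), gff)
    gm <- readGeneModels(gff)
    expect_identical(length(gm), 1L)
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("A", 10), "ATGGGATGGTGGTGA", strrep("C", 10))))
    ann <- annotateVariants(VariantSites("chr1", 16L, "A", "G"), gm, ref)
    expect_identical(ann$category, "synonymous")
    expect_identical(ann$gene_id, "g1")
})

test_that("per-gene summaries and densities follow the coverage arithmetic", {
    ref <- Biostrings::DNAStringSet(c(chr1 = paste0(
        strrep("A", 10), "ATGGGATGGTGGTGA", strrep("C", 10))))
    gm <- geneModels(list(toyGene("g1", "chr1", 11L, 15L)))
    # 2 coding SNPs in g1: one synonymous, one stop gain
    vs <- VariantSites("chr1", c(16L, 22L), c("A", "G"), c("G", "A"))
    ann <- annotateVariants(vs, gm, ref)
    covered <- c(g1 = 2000, g2 = 500)
    summ <- geneVariantSummary(ann, covered)
    expect_identical(nrow(summ), 2L)
    g1 <- summ[summ$gene_id == "g1", ]
    expect_identical(g1$n_coding, 2L)
    expect_equal(g1$density_per_kbp, 1.0)
    expect_identical(g1$synonymous, 1L)
    expect_identical(g1$nonsense, 1L)
    # a covered gene with no variants gets an all-zero row
    g2 <- summ[summ$gene_id == "g2", ]
    expect_identical(g2$n_coding, 0L)
    expect_equal(g2$density_per_kbp, 0)
    # 10 coding SNPs over 2000 bp is 5 per kbp
    expect_equal(10 * 1000 / 2000, 5)
    # genome-scale density arithmetic
    expect_equal(genomeSnpDensity(32e6, 400e6), 12.5)
    expect_equal(genomeSnpDensity(1, 1000), 1000)
    expect_equal(round(genomeSnpDensity(2614, 72000), 1), 27.5)
    expect_error(genomeSnpDensity(0, 1000), "positive")
})

test_that("annotating the reference allele against itself is rejected", {
    expect_error(VariantSites("chr1", 16L, "A", "A"), "differ")
})
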
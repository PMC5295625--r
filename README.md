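# ampliPool

Variant curation for pooled amplicon resequencing in R.

## The problem

Allele mining in large germplasm collections is often done by *pooled
targeted resequencing*: DNA from hundreds of accessions is combined into a
few pools, candidate-gene exons are PCR-amplified (~600 bp amplicons) and
deep-sequenced (per-region depths of order 10⁴), and population allele
frequencies are estimated from per-allele read counts instead of individual
genotypes. In a pool of *N* diploids the smallest real minor allele
frequency is 1/(2*N*) — 1/400 = 0.0025 for 200-sample pools — so a true
singleton allele at 10,000× depth is supported by only ~25–100 reads, a
signal easily confused with base-call errors. Separating those two is the
central statistical problem this package addresses, for scientists running
or re-analysing pooled amplicon experiments (Ecotilling-style allele
mining, mutation screens, pool-seq surveys).

## What the package does

- **Region QC** (`assignFragments`, `captureRate`, `regionDepthTable`):
  assigns aligned fragments to primer-defined target regions by ≥ 90%
  reciprocal overlap, computes the capture success rate, and flags
  region/pool pairs with fewer than 20 fragments.
- **Multi-caller merging** (`readCallset`, `mergeCallsets`,
  `intersectionSummary`, `alignerConsistency`, `overlapWithReference`):
  reads VCFs from several aligner × caller discovery pipelines, left-aligns
  and minimally represents alleles, takes the provenance-tracked union, and
  summarises tool intersections.
- **Pooled frequencies** (`countAlleles`, `alleleFrequency`,
  `adjustedFrequency`, `poolFrequencyRanges`): per-pool per-allele read
  counts (pileup for SNPs, exact span matching for indels), adjusted
  frequencies over the two predicted alleles, and cross-pool consistency
  ranges flagged at 0.05 and 0.1.
- **The error-ratio filter cascade** (`estimateErrors`, `errorRatio`,
  `applyCascade`): the per-site sequencing-error support is estimated as
  the mean of the two smallest of the four nucleotide counts, and a site is
  kept only when its second-ranked allele count is at least 5× that
  estimate:

  ```
  err(site)   = (n(3) + n(4)) / 2        n(1) ≥ n(2) ≥ n(3) ≥ n(4)
  ratio(site) = n(2) / err(site)         keep iff ratio ≥ 5
  ```

  applied after removing SNPs embedded in indels, keeping biallelic SNPs,
  and requiring ≥ 10,000× summed depth and presence in ≥ 2 pools. Every
  stage's attrition is reported.
- **Consequence annotation** (`annotateVariants`, `geneVariantSummary`):
  codon-level classification (synonymous / missense / nonsense / stop_lost
  / frameshift / inframe) against GFF3 gene models, with per-gene SNP
  densities per covered exonic kbp.
- **Synthetic data & power** (`simConfig`, `simulatePools`,
  `simulateFragments`, `simulateCallsets`, `detectionPower`): a seeded
  generator reproducing the pooled design (8 pools × 200 diploids, 600 bp
  amplicons, ~20,000× depth, rare-dominated frequency spectrum,
  caller-specific MAF sensitivity) plus Monte-Carlo detection power of the
  full cascade.
- **Pipeline driver** (`readRunConfig`, `runQc`, `runCuration`,
  `runAnnotation` and the `inst/scripts/amplipool.R` CLI) for
  config-driven, reproducible end-to-end runs.

## Worked example

The statistic in one line — read counts of a strongly pool-discordant SNP,
alternative allele G, pool 4 vs pool 8:

```r
library(ampliPool)
pool4 <- c(A = 989,   C = 0, G = 27876, T = 0)
pool8 <- c(A = 13028, C = 9, G = 6,     T = 13)
adjustedFrequency(pool4, "A", "G")   # 0.9657371
adjustedFrequency(pool8, "A", "G")   # 0.0004603345
estimateErrors(pool8)                # 7.5   = (9 + 6) / 2
errorRatio(pool8)                    # 1.733 = 13 / 7.5  -> below 5, filtered
```

In pool 4 the G allele is real (96.6% of the informative reads); in pool 8
its 6 reads sit *below* the site's error level (7.5 reads, estimated from
the C and T counts), so the pool-8 signal is sequencing noise.

End-to-end on simulated data:

```r
cfg <- simConfig(n_sites = 200, seed = 42)   # 8 pools x 200 diploids, 20,000x
sim <- simulatePools(cfg)
res <- applyCascade(sim$sites, sim$counts, filterConfig())
res$report
#>              filter sites_in sites_removed sites_out
#> 1 embedded_in_indel      200             0       200
#> 2     biallelic_snp      200             0       200
#> 3         min_depth      200             0       200
#> 4         min_pools      200             0       200
#> 5       error_ratio      200            15       185
```

All 69 planted common variants survive; the 15 casualties are rare alleles
near the single-carrier floor, exactly where the error-ratio filter is
expected to trade sensitivity for specificity:

```r
detectionPower(20000, 0.0025, 0.002, n_reps = 500, seed = 7)$power  # 0.268
detectionPower(20000, 0.01,   0.002, n_reps = 500, seed = 7)$power  # 1
```

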
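---
title: "Curating variants from pooled amplicon resequencing"
author: "ampliPool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating variants from pooled amplicon resequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ampliPool)
```

# The data model

Pooled amplicon resequencing trades individual genotypes for population
allele frequencies. DNA from roughly 200 diploid samples is combined per
pool (8 pools here), candidate-gene exons are amplified as ~600 bp
amplicons and sequenced to per-region, per-pool depths of order 10^4. At a
variant site, the read count of each allele in a pool is then — to a good
approximation — a multinomial draw whose alternative-allele probability is
the pool's allele fraction, perturbed by base-call errors. Everything this
package does rests on that single sufficient statistic: the per-pool,
per-allele read count table (`PoolCounts`, a
`RangedSummarizedExperiment` with one assay per nucleotide).

Two design numbers anchor the scale of the problem. A variant carried
heterozygously by one sample in a 200-sample diploid pool has frequency
`theoreticalMinMaf(200, 2)` = 1/400 = 0.0025; and an allele at frequency
0.01 sequenced at 10,000x is expected in `expectedMinorReads(10000, 0.01)`
= 100 reads. Rare real alleles therefore live only a small factor above
the error floor, which is what makes principled filtering necessary.

# Stage by stage

## Fragment-to-region QC

A sequenced fragment (the span of a properly paired, uniquely mapped read
pair) is assigned to a target region when the overlap covers at least 90%
of the fragment *and* 90% of the region, both inclusive. The boundary is
read inclusively because "requiring 90%" conventionally means "at least
90%"; with equal 600 bp lengths an overlap of exactly 540 bp qualifies.
When two overlapping amplicons both qualify, the assignment with the
larger product of the two overlap fractions wins and an exact tie leaves
the fragment unassigned — reciprocal overlap at 90% makes double
qualification geometrically rare, and the product rule makes uniqueness
deterministic without favouring either endpoint. The capture success rate
divides assigned fragments by *all* fragments, improper and multi-mapping
pairs included, so it measures the experiment, not the aligner's mood.
Region/pool pairs with fewer than 20 assigned fragments (strictly less)
are flagged as failed or weak primers.

Paired-end trimming leaves reads of unequal length (240 bp and 170 bp
after quality trimming in the motivating design), so a 600 bp amplicon has
`coverageGap(600, 240, 170)` = 190 bp of central sequence that no read
covers; the QC stage reports this arithmetic per amplicon length.

Internally all coordinates are 1-based inclusive (the GRanges convention);
BED input/output converts from 0-based half-open at the boundary, through
`rtracklayer`.

## Merging callsets with provenance

Different variant callers represent the same indel differently, so before
any set arithmetic each allele pair is normalized: shared trailing bases
are trimmed (extending leftward with reference sequence when an allele
would empty), then shared leading bases are trimmed. This is the standard
left-alignment / minimal-representation procedure; the test suite checks
it with an oracle that treats two representations as equivalent exactly
when they produce the same edited sequence. Without normalization a union
over seven callers systematically overcounts.

Sites are fused on (chrom, pos, ref). A position where one caller saw
`A>G` and another `A>T` becomes one multiallelic site — classification is
a property of the *merged* evidence, not of any single caller's record.
Provenance (the set of pipeline ids calling each site) drives the
intersection summary, per-caller cross-aligner consistency (Jaccard of the
two aligner-specific callsets) and the overlap against an external
reference panel, stratified by MAF bin.

## Frequencies and the error-ratio filter

The raw frequency of an allele is its count over the total depth; the
*adjusted* frequency divides the alternative count by reads supporting
only the two predicted alleles, excluding error-allele reads from the
denominator. Zero-depth pools report `NA`, never 0, so cross-pool ranges
are not artificially deflated. Because pools are drawn from one population
without structure-aware assignment, per-pool frequencies of a real variant
should agree; the range between the largest and smallest per-pool estimate
is reported and flagged above 0.05 and 0.1.

The curation cascade runs in a fixed order:

1. remove SNPs whose position falls inside the reference span
   `[pos, pos + nchar(ref) - 1]` of any indel site (alignment artefacts);
2. keep biallelic SNPs;
3. require total read depth ≥ 10,000 (summed across pools by default);
4. require ≥ 1 alternative read in ≥ 2 pools;
5. require an error ratio ≥ 5.

The error statistic is the cascade's core. At a SNP site only four
nucleotide counts exist and at most two belong to real alleles, so the
counts ranked third and fourth in descending order can only be sequencing
errors; their mean estimates the per-allele error support, and the ratio
of the second-ranked count to that estimate measures how clearly the minor
allele rises above noise. A literal ascending reading of "third and fourth
smallest" would average the major allele into the error estimate and
cannot estimate errors; the implementation therefore uses the two smallest
counts, with ties broken alphabetically for determinism. When the estimate
is zero, a positive second count passes cleanly (ratio `Inf`) and a zero
second count fails (a site with no minor support is not a variant).

Ambiguities the source description leaves open are configuration, not
hard-coding (`filterConfig()`): whether depth and the error statistic
aggregate across pools (`summed_across_pools`, the default — the error
estimate is described per variant, not per pool) or must hold in some
single pool (`per_pool_any`); how many alternative reads make a variant
"present" in a pool (default 1); the ratio threshold; and the error ranks
themselves.

## Consequence annotation

Coding SNPs are classified by translating the reference and alternative
codons (reverse-complemented on minus-strand genes, reading frame from the
CDS phase, standard nuclear codon table, start codons treated as ordinary
codons): synonymous, missense, nonsense, or stop_lost. CDS indels are
frameshift when their length change is not a codon multiple, otherwise
inframe insertion/deletion with affected residues named. SNPs in introns
and outside genes are classified as such; exonic positions outside any CDS
(UTRs) get their own `noncoding_exon` category rather than being forced
into intron or intergenic. Where several transcripts overlap, each is
annotated and the per-site summary takes the most severe category
(frameshift/nonsense > stop_lost > missense > inframe > synonymous >
noncoding_exon > intron > intergenic). Per-gene summaries count coding
variants by category and report density as variants × 1000 / covered
exonic bp, omitting (with a warning) genes without coverage information
and emitting all-zero rows for covered genes without variants.

# The simulator

`simulatePools()` emulates the experiment's statistical structure, not its
reads: per site a population frequency is drawn from a rare-dominated
mixture (65% of sites uniform on [1/400, 0.01], the rest uniform on
[0.01, 0.5] — echoing the observation that pooled deep sequencing of
hundreds of accessions is dominated by rare alleles); per pool, carrier
allele copies are binomial over 400 chromosomes (pools are drawn
independently, matching pooling without structure information); reads are
multinomial over the four nucleotides at the pool's allele fraction; and
each read is corrupted to a uniformly chosen other base with probability
0.002 (configurable — the motivating experiment reports no empirical
post-trim error rate, and 0.1–0.5% is the usual short-read substitution
range). `fixed_pool_fraction` bypasses the carrier draw for calibration
experiments. Everything is a deterministic function of the mandatory seed.

`simulateFragments()` plants a configurable on-target fraction (default
0.91) with the remainder split between improper pairs, multi-mappers and
off-target placements, exercising the QC path.  `simulateCallsets()`
writes one VCF per simulated pipeline; a pipeline calls a site when the
mean pool fraction reaches its detection floor, plus Poisson false
positives (rate = expected FPs per true site). The default roster crosses
two aligner labels with three caller profiles whose floors (0.0025, 0.02,
0.05) mimic the spread between pool-aware and conventional callers.

What the simulator deliberately does **not** model: sequencer-specific or
position-dependent error profiles, PCR duplicates and chimeras, alignment
errors around indels, and coalescent population structure. Passing tests
therefore demonstrate the pipeline's statistical behaviour under its own
assumptions — unbiased multinomial sampling with uniform errors — not
robustness to every artefact of real data.

## Detection power

`detectionPower()` Monte-Carlo-estimates the probability that a planted
SNP at a given within-pool allele fraction survives the whole cascade. It
simulates at a *fixed* pool fraction rather than redrawing carriers, so
the estimate isolates the read-level statistic's power from
carrier-sampling noise; at the single-carrier floor the carrier draw is
itself the dominant uncertainty, and mixing the two would make the power
surface much harder to interpret. Power is high (≈ 1) for alleles at
frequency ≥ 0.01 under the design depth and error rate, drops steeply
toward the 0.0025 floor, and is ≈ 0 for pure-error sites — the
quantitative form of the observation that low-frequency alleles become
inseparable from sequencing errors.

# Numerical choices and degenerate inputs

* Frequencies at zero depth are `NA` (missing), never 0; ranges over fewer
  than two informative pools are `NA`.
* Error-rank ties break by alphabetical allele order, making the statistic
  deterministic.
* Base-quality cutoff for SNP counting defaults to Phred 20 — a standard
  choice that keeps trim-end errors from dominating counts; the source
  procedure states none.
* Indel allele counting demands an exact match of the read's implied
  haplotype over the reference span; soft-clipped or partially spanning
  reads are excluded. Conservative, and exactly testable.
* The recovery guarantee `|f_hat − f| ≤ 4·sqrt(f(1−f)/depth)` is checked
  on estimates whose true pool fraction is positive: at f = 0 the band has
  zero width and a single error read would violate it by construction.
* Variants spanning a CDS boundary are classified by the CDS portion they
  affect; splice-site categories are not modelled.

# Problem sizes

The test suite and acceptance script run at desk scale, chosen as the
smallest sizes at which the statistical assertions are stable: 1000 sites
× 8 pools at 5,000× for frequency recovery, 400 sites at 20,000× for the
filter's specificity/sensitivity (each bound holds with wide margin —
the binomial SE at 400 replicates is about 1%), 100–500 Monte-Carlo
replicates for power curves, and 10^5 fragments for the capture-rate
check. The statistical conclusions are insensitive to scaling these up.

# Known limitations

Pooled designs cannot genotype individuals, phase haplotypes, or
distinguish one homozygous carrier from two heterozygous ones; nothing
here attempts imputation. The cascade's sensitivity floor is set by the
error-ratio threshold: at the single-carrier frequency the filter
sacrifices most true singletons to keep the false-positive rate near zero,
which is the intended trade for follow-up genotyping. Upstream caller
biases (a pool-aware caller will dominate the union at low MAF) are
reported via provenance but not corrected.
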
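Package: ampliPool
Title: Variant Curation for Pooled Amplicon Resequencing
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to curate variants discovered from pooled targeted
    amplicon resequencing experiments, where DNA from hundreds of
    individuals is sequenced together and allele frequencies are
    estimated from read counts rather than genotypes. Implements
    fragment-to-amplicon assignment by reciprocal overlap with capture
    and coverage QC, merging of variant callsets from multiple
    aligner/caller pipelines with per-pipeline provenance, pooled
    per-allele read counting and adjusted allele-frequency estimation,
    a sequencing-error-ratio filter cascade for separating rare alleles
    from base-call errors, cross-pool frequency consistency analysis,
    functional consequence annotation against gene models, and a
    synthetic pooled-sequencing generator with detection-power
    estimation for experimental design.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    Rsamtools,
    GenomicAlignments,
    VariantAnnotation,
    rtracklayer,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
biocViews: Sequencing, VariantDetection, VariantAnnotation, QualityControl
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'ampliPool-package.R'
    'variant-sites.R'
    'vcf-io.R'
    'annotation.R'
    'callset-merge.R'
    'pool-counts.R'
    'curation-filters.R'
    'regions-qc.R'
    'pipeline.R'
    'synthetic-data.R'
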
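Package: autozygR
Title: Runs of Homozygosity and Autozygosity Mapping from Multi-Sample VCFs
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects runs of homozygosity and autozygous (shared
    identical-homozygous-genotype) regions in affected individuals from
    multi-sample VCF files, as used in homozygosity mapping of autosomal
    recessive disease in consanguineous families. Genotypes of single
    nucleotide variants are stored in a compact bit-coded matrix; no-calls
    and low-coverage genotypes are treated as homozygous wildcards so that
    hemizygous stretches and homozygous deletions surface as runs. Shared
    regions are scored by a per-marker homozygosity score, ranked by
    physical length, and exported as BED intervals and region-restricted
    VCF files (including InDels) for downstream disease-mutation
    filtering. Includes a synthetic pedigree VCF simulator with planted
    identity-by-descent segments for validation, genome-wide score plots
    and per-region genotype grids.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    vcfR,
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: SNP, VariantAnnotation, Genetics, Sequencing
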
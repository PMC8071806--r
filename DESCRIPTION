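Package: erodr
Title: Genomic Erosion Analysis for Small and Endangered Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying genomic erosion in small, fragmented
    populations from multi-sample variant data: site filtering (coverage,
    quality, indel proximity, CpG/repeat/sex-scaffold masks), genome-wide
    heterozygosity, runs-of-homozygosity inbreeding coefficients (F_ROH),
    GERP-weighted relative mutational load with fixed-depth allele
    subsampling of shared and private deleterious alleles, loss-of-function
    variant burden and translocation-risk estimation for assisted gene
    flow, and a per-gene population branch statistic (PBS) selection scan.
    Includes a synthetic-data generator with known ground truth (planted
    identity-by-descent tracts, Balding-Nichols population divergence,
    per-site conservation scores and effect categories) so every analysis
    stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    IRanges,
    jsonlite,
    methods,
    stats,
    utils,
    vcfR
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr,
    yaml
VignetteBuilder: knitr
Config/testthat/edition: 3
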
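Package: rohscan
Title: Runs of Homozygosity, Genomic Inbreeding and ROH-Based Population
    Structure from SNP-Array Genotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for the genomic characterization of
    populations from SNP-array genotypes in PLINK text format: quality
    control and dataset construction robust to ascertainment bias,
    rule-based detection of runs of homozygosity (ROH), per-animal and
    per-group ROH statistics including the genomic inbreeding coefficient
    F_ROH, scanning for ROH islands from the per-SNP ROH incidence,
    an identical-by-state ROH-coded genomic relationship matrix (VanRaden
    scaling) with eigen-analysis of population structure, Wright's F_ST
    with LOWESS smoothing and outlier calling, and per-SNP logistic
    regression of ROH membership on group. A synthetic genotype generator
    with planted autozygous segments and full ground truth supports
    end-to-end validation without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
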
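Package: coldrank
Title: Ranking DNA Variants for Body-Temperature Maintenance Under Cold
    Stress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Identifies candidate DNA loci affecting body-temperature
    maintenance under acute cold stress from whole-genome resequencing of
    phenotypic extremes. Computes an area-under-the-curve phenotype from
    in-ear temperature sensor series, selects breed-balanced extreme
    groups, applies GATK-style hard filters to variant calls, estimates
    Weir-Cockerham F_ST per site and in sliding windows, integrates window
    F_ST, group allele-frequency differences and per-SNP functional scores
    into fractional-rank sums for candidate selection, and classifies
    candidates by coding consequence. Includes a synthetic-study generator
    with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    graphics,
    rtracklayer,
    stats,
    utils,
    vcfR
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
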
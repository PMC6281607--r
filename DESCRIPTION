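Package: geneburden
Title: Gene-Level Rare-Variant Collapsing Burden Analysis for Case-Control Exome Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for gene-level rare-variant collapsing
    burden analysis in case-control whole-exome sequencing studies. Provides VCF
    cohort loading with multi-allelic splitting and indel left-alignment, a
    genotype/variant/sample quality-control cascade (depth and genotype-quality
    masking, missingness, exact Hardy-Weinberg test, differential missingness,
    allele balance, relatedness, region masks), consensus damage classification
    of variants into protein-truncating and missense deleteriousness tiers,
    per-gene carrier-collapsing Fisher exact tests with Bonferroni and FDR
    adjustment, an aggregated allele-count comparison against an external
    reference panel with a per-gene robustness verdict, and a synthetic-cohort
    generator for validation and power studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    vcfR,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
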
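Package: rumiquant
Title: Quantitative Metatranscriptomics of the Rumen Microbiome
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Converts relative rRNA and mRNA read counts from rumen fluid
    metatranscriptomes into absolute transcript copies per gram of rumen
    fluid, aggregates quantified mRNA into carbohydrate-active enzyme
    (CAZyme) categories, volatile fatty acid (VFA) production pathways and
    methanogenesis marker genes, and links microbiome profiles to rumen
    process data (VFA concentrations, pH, gas emissions) with
    permutation-based community statistics (PERMANOVA, indicator analysis)
    and paired tests. Includes a synthetic feeding-trial generator that
    emulates the post-classification count tables of a 4-cow, 4-timepoint
    diurnal feeding experiment so the full pipeline is testable without
    sequence data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vegan
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
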
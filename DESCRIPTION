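Package: markermine
Title: Guilt-by-Association Mining of Secreted Disease Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands small sets of subtype-specific seed marker genes through
    three orthogonal evidence axes (transcription-factor regulation, pathway
    co-membership, co-expression and protein interaction), combines evidence
    sources by union within an axis and intersection across axes, filters
    candidate proteins for extracellular targeting by signal-peptide and
    transmembrane topology, validates predictions by paired tumor/normal
    differential expression, and summarizes validated gene lists with
    hypergeometric over-representation statistics. Includes readers for local
    knowledge-base extracts (TSV edge tables, GMT gene sets, Phobius short
    topology output), a synthetic-data generator with planted ground truth for
    end-to-end testing, and ggplot2 visualizations of the results.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
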
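Package: mucoferm
Title: Metaproteomic Profiling and Culture Physiology of Mucin and Fiber Fermentations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-search analysis of fecal-community fermentation metaproteomics:
    in-silico tryptic digestion and peptide-uniqueness indexing of taxon-labeled
    proteomes, de novo-guided refinement of the protein search database,
    community composition from the relative intensity of taxon-unique peptides,
    consensus carbohydrate-active enzyme (CAZyme) annotation and sequence-based
    metabolic mapping with per-group enzyme copy numbers, culture-physiology
    calculations (biomass from calorimetric heat, dissolved gases by Henry's law
    with pH-dependent speciation, metabolite normalization to dry weight, and a
    stoichiometric mucin-proline propionate bound), and the nonparametric
    community statistics stack (Gini-Simpson, Bray-Curtis, principal
    coordinates, Kruskal-Wallis with Dunn's post hoc and Benjamini-Hochberg
    correction). A synthetic-community generator with known ground truth makes
    the whole pipeline testable end to end without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    Biostrings,
    dplyr,
    pracma,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
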
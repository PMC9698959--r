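Package: metabotalent
Title: Strain Prioritization from Untargeted LC-MS/MS Metabolomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Downstream analysis of untargeted LC-MS/MS metabolomics for
    microbial strain collections: reads MZmine-style feature quantification
    tables and MGF fragmentation spectra, computes presence/absence occurrence
    analytics across taxonomic groups (Venn partitions, strain-specific feature
    counts, uniqueness-isolate correlation), builds feature-based molecular
    networks from a modified-cosine spectral similarity with mutual top-k edge
    pruning and molecular-family size capping, runs a three-level dereplication
    cascade (in-house standards, external spectral libraries, in-silico
    structure candidates) with family-level chemical-class propagation, and
    ranks "talented" producer strains by metabolite uniqueness and unknown
    fraction. A seeded synthetic-cohort generator with planted feature strata
    and spectral families makes every stage testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    readr,
    igraph,
    ggplot2,
    generics,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
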
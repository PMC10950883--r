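Package: nitrocat
Title: Cataloging and Spectral Validation of Nitrotyrosine Peptides from
    Antibody-Based Enrichment Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Downstream analysis of immunoaffinity-enriched 3-nitrotyrosine
    (nitroY) proteomics experiments. Provides monoisotopic mass and b/y
    fragment-ion arithmetic for modified peptidoforms, readers and writers
    for MGF peak lists, FASTA databases and peptide-spectrum-match tables,
    cosine spectral similarity between experimental and synthetic peptide
    spectra (base-peak filtering, tolerance peak matching, mirror plots),
    nitration-site cataloging with N-terminal-position statistics,
    cross-antibody overlap analysis, flanking-sequence motif matrices, and
    a ground-truthed synthetic-data generator that emulates protein- and
    peptide-level enrichment so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
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
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
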
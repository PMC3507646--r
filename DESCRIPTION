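Package: matchratio
Title: Amino Acid Substitution Flexibility from Comparative Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies how freely proteins accept amino-acid substitutions
    between the unigene sets of two related species. Translated local
    alignment (six reading frames, BLOSUM62) stands in for TBLASTX-style
    searches at desk scale; alignment columns are classified into identical
    matches, homologous (conservative) substitutions, mismatches and gaps,
    and the identical match ratio i/(i+h) scores each homologous pair.
    Ranked pairs are split into high- and low-substitution extremes and
    cross-tabulated against functional classes with log2 odds; ontology
    edge lists drive gene-set extraction with descendant roll-up; an OR
    rule over homology-search channels calls per-dataset gene conservation;
    and EST-collection summaries (assembly statistics, depth histograms,
    rarefaction curves) complete the pipeline. Synthetic-data generators
    with known ground truth make every stage testable without external
    databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
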
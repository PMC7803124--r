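Package: rumenAKP
Title: Microbiome Dynamics and Fermentation Analysis for In-Vitro Rumen
    Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of 16S rRNA OTU tables and fermentation measurements
    from semi-continuous in-vitro rumen (RUSITEC) experiments comparing
    seaweed-amended and control vessels. Provides mothur-compatible I/O
    (shared/taxonomy/PHYLIP distance formats), rarefying and rank
    aggregation, alpha-diversity indices (Chao1, Good's coverage, Shannon,
    inverse Simpson), Bray-Curtis/Jaccard/Yue-Clayton dissimilarities,
    AMOVA/HOMOVA permutation tests and principal coordinate analysis on
    distance matrices, Anna-Karenina beta-diversity trajectory analysis with
    permutation slope tests and cluster-bootstrap confidence intervals, gas
    and volatile fatty acid summaries with vessel-level permutation
    contrasts, and a Dirichlet-multinomial synthetic-data generator that
    emulates the experimental design for testing and power analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
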
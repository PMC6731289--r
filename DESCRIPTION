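Package: biogasnet
Title: Methanogenic Pathway Classification and Ensemble Co-Occurrence
    Networks for Biogas-Plant Metaproteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream analysis of protein-group
    relative-abundance tables from anaerobic digester (biogas plant)
    metaproteomes. Classifies the dominant methanogenic pathway of each
    sample or plant from the ratio of acetoclastic-unique to
    hydrogenotrophic-unique KEGG orthology (KO) protein abundances
    (factor F), infers co-presence/mutual-exclusion networks at species
    level with an ensemble of correlation and dissimilarity measures,
    bootstrap significance, Brown's method for combining dependent
    p-values and Benjamini-Hochberg control, assigns Guimera-Amaral
    topological roles (within-module degree z, participation
    coefficient), screens abundances against process metadata
    (Spearman) and metadata collinearity (VIF), and ships a synthetic
    data generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    vegan,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
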
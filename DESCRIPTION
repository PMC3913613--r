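Package: oralclust
Title: Consensus Clustering and Diversity Analysis of Oral Biofilm
    Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal 16S rRNA gene community
    profiles of maturing oral biofilms. Reads mothur 'shared' count tables
    and 'constaxonomy' files, rarefies to a common depth, and collapses
    OTUs to taxon-level relative abundances. Provides Hill-number alpha
    diversity with a mixed-effects time model, Hellinger-transform partial
    redundancy analysis with stratified permutation tests, Monti-style
    consensus clustering (CDF-area cluster-number selection, item-consensus
    robustness filtering) of species and of subjects, rank-based
    association statistics (Spearman distances, RV coefficient, ANOSIM),
    and a Dirichlet-multinomial community simulator with planted cluster
    structure for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    cluster,
    jsonlite,
    lme4,
    lmerTest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
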
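Package: rqcensus
Title: Rule-Based Phylogenomic Census of Bacterial Ribosome Rescue Factors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies bacterial proteins as the ribosome rescue and
    ribosome-associated quality control factors YlmH, RqcH, RqcP, Hsp15 or
    SmpB using profile bit-score gates, a domain-exclusion cascade and
    aligned-residue motif rules anchored in reference (B. subtilis)
    numbering, then aggregates presence/absence per genome and per phylum
    into incidence percentages and co-distribution summaries. Includes a
    position-specific log-odds profile engine with a local affine-gap
    aligner, adapters for HMMER3 domtblout scores and Pfam gathering
    cutoffs, and a synthetic proteome generator with planted truth labels
    for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports: Rcpp, yaml, stats, utils, tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
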
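Package: kvancestry
Title: Ancestral Voltage-Gated Potassium Channel Reconstruction from Gene
    Phylogenies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the voltage-gated potassium (Kv, EAG, KCNQ) channel
    gene set of ancestral lineages from protein sequences and
    support-annotated gene phylogenies. Classifies candidate channel proteins
    into families and subfamilies by reciprocal best-hit local alignment
    against annotated references with diagnostic-domain and completeness
    filters; counts ancestral genes as the minimal clades of a gene tree that
    contain members of two focal lineages with adequate node support; scores
    degeneration of the S6 activation gate to flag putative regulatory
    (R-type) subunits; and tabulates per-species counts and ancestral
    presence/absence matrices. A duplication-loss simulator generates gene
    trees, supports and domain-bearing protein sequences with known ancestral
    truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    withr,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
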
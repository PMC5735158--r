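Package: scptools
Title: Population, Relationship Inference and Dynamic Enrichment for
    Hierarchical Subcellular-Process Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for building and analysing hierarchical ontologies of
    subcellular processes (SCPs). Populates a 5-level SCP taxonomy with genes
    from literature mention counts via two-stage competitive Fisher
    enrichment with largest-gap cutoffs, incorporates manual-validation
    labels, infers weighted SCP-SCP relationships by leave-one-out
    competition for genes, and runs standard and dynamic (unit-merging)
    enrichment analyses in which whole-cell functions emerge as connected
    SCP networks. Includes dictionary-based gene mention counting in
    abstract sets, internal-consistency quality control, co-expression
    validation of gene-SCP associations, and seeded synthetic fixture
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
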
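Package: orthomeld
Title: Consensus Ortholog Compendia from Multiple Prediction Programs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Integrates ortholog predictions from several orthology-detection
    programs into a consensus compendium with per-gene source support, in the
    style of meta-analyses comparing the C. elegans and human genomes. Parses
    four flat-file prediction dialects (pairwise clusters, group lines,
    homology groups and ortholog pairs), harmonizes gene identifiers against
    merge/removal/pseudogene status maps, computes Venn partitions and
    inter-program congruence statistics, extracts gene families by
    InterPro/GO term rules with auditable manual-correction ledgers,
    evaluates them against gold-standard family compendia, and quantifies
    how well the consensus covers RNAi-screen hit lists and clone libraries.
    A synthetic-data module simulates two genomes related by speciation with
    duplications and noisy per-source predictions so the whole pipeline is
    testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
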
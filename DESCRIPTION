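Package: mirexo
Title: Milk-Exosome Small RNA Profiling Pipeline
Version: 0.1.0
Authors@R: person("mirexo", "maintainers", email = "mirexo@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable pipeline for milk-exosome small RNA
    sequencing data: adapter trimming and junk/contaminant filtering of raw
    reads into unique 18-26 nt tags with per-sample copy numbers, known and
    novel miRNA identification against miRBase-style precursor references
    with an eleven-criterion hairpin secondary-structure screen,
    median-reference regression normalization of copy numbers, two-group
    differential miRNA expression calling, seed-match target prediction with
    dual-threshold intersection filtering, hypergeometric GO/KEGG enrichment,
    and two-sample milk-composition comparisons. Ships deterministic, seeded
    synthetic-data generators with machine-readable truth tables so every
    stage can be validated without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
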
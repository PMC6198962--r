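Package: chlorotypr
Title: In Silico PCR-RFLP Chlorotyping of Chloroplast Non-Coding Regions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for chloroplast DNA haplotyping (chlorotyping) by in-silico
    PCR-RFLP: virtual amplicon extraction from templates, restriction-site
    scanning with degenerate (IUPAC) recognition motifs, fragment prediction,
    and encoding of per-sample digest outcomes as ordered binary chlorotype
    strings. Includes discovery of new diagnostic restriction sites (CAPS
    markers) from aligned sequence sets, population statistics on grouped
    chlorotype collections (Pearson chi-square tests, analysis of molecular
    variance with Monte-Carlo permutation, per-group diversity contributions),
    minimum spanning haplotype networks with tie retention and eigenvector
    centrality, and seeded generators of synthetic sequence collections with
    controlled digest states for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    ade4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
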
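Package: statscreen
Title: Multi-Target Virtual-Screen Triage and Genome-Wide Inhibition Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for triaging multi-target virtual-screening output and for
    downstream genome-wide inhibition analysis of STAT-pathway inhibitors.
    Implements best-pose selection, comparative binding affinity values (CBAV),
    ligand binding pose variation (LBPV), similarity and molecular-weight
    filters, and mutant delta-delta-G impairment calls on docking score tables;
    a microarray-style expression pipeline (flooring, log transform,
    background subtraction, quantile normalization, fold-change induction
    filtering, the FC-ratio inhibition criterion, and multi-inhibitor Venn
    intersections); MATCH-style position-weight-matrix promoter scanning with
    ISRE/GAS/NF-kB combination classification; small calculators for qPCR,
    ChIP and wound-healing readouts; and seeded synthetic-data generators so
    the whole pipeline is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    limma,
    Biostrings,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
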
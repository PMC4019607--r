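Package: mirlink
Title: miRNA-mRNA Functional Link Prediction for Differentiation Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts functional microRNA-target links from a differentiation
    time course. Expression trajectories are normalized to an uncultured
    control condition and filtered by fold change, candidate targets are found
    by canonical seed-site matching (8mer, 7mer-m8, 7mer-A1, 6mer) in 3'UTR
    sequences with a context-style site score and duplex-alignment refinement,
    target genes are restricted by exact annotation-term matching, pathways
    are ranked by a right-tailed Fisher exact test, and miRNA-target network
    edges are gated on temporal Pearson anti-correlation. A synthetic-data
    generator emulates the bone-marrow culture time-course design (uncultured
    control plus six timepoints, replicate cultures, planted effects) with
    ground-truth sidecars so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    fgsea,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
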
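Package: scIgRep
Title: Single-Cell Immunoglobulin Heavy-Chain Repertoire Simulation and Annotation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing IgG heavy-chain V(D)J rearrangements in
    single cells sequenced by colony cloning and Sanger sequencing. Provides a
    curated germline V/D/J reference container, a V(D)J recombination simulator
    with N-nucleotide junctions, hotspot-biased somatic hypermutation and
    controlled clonal sharing, an alignment-based germline assignment and
    junction/CDR3 annotator with productivity classification,
    somatic-hypermutation analysis (RGYW/WRCY hotspot motifs, CDR versus
    framework mutation concentration), and repertoire-level statistics:
    segment-usage tables with chi-square comparison, rearrangement patterns per
    cell, shared identical-junction clonotype detection, CDR3 length
    distributions with Gaussian fits, and genomic-position bias of V-gene
    usage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    Biostrings,
    IRanges,
    S4Vectors,
    jsonlite,
    minpack.lm,
    optparse,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
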
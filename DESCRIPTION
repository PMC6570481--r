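Package: oplsmotif
Title: Kinase Substrate Motifs from Oriented Peptide Library Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for oriented peptide library screening (OPLS)
    of protein kinases. Normalizes raw spot-intensity grids into
    position-specific phosphorylation-site motifs (column-mean normalization,
    replicate averaging, capping of acceptor-like fixed residues, log2
    transformation), clusters kinases by motif similarity (one-minus-Pearson
    distance, average linkage) or by kinase-domain sequence identity, builds
    position-specific scoring matrices and scores candidate phosphosites
    Scansite-style (lower is better, 0 is a perfect match), selects
    percentile-based target sets and computes their multi-kinase overlap,
    extracts residues at fixed offsets from conserved kinase-domain anchors
    (HRD, DFG, APE), and estimates peptide-phosphorylation rates as linear
    regression slopes of scintillation time courses. Includes a synthetic
    data generator with known ground-truth motifs so the whole pipeline is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    Biostrings,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
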
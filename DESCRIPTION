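Package: kappaBarray
Title: Protein Binding Microarray Design and Binding-Profile Analysis for
    NF-kB Family Dimers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing degenerate-consensus protein binding
    microarrays (PBMs) and analysing the binding profiles they produce.
    Expands an IUPAC kappaB consensus into its k-mer space, picks a
    representative probe-core subset by principal coordinate analysis and
    k-medoids, assembles the physical array design, and simulates
    two-channel (Cy3/Cy5) intensities from position-weight-matrix
    occupancy ground truth. Implements the Cy3 normalisation, log2
    replicate-median and array z-score chain, cross-protein profile
    correlation and complete-linkage clustering, and top-N binding
    "barcode" construction (position frequency matrix, information
    content, half-site symmetry), plus plate-level quantification
    statistics for LUMIER fold-binding, dual-luciferase reporter
    fold-induction and ChIP-qPCR fold-enrichment over IgG.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    cluster,
    ape,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
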
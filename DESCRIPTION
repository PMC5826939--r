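Package: hepatoquant
Title: Quantitative Assessment of Hepatic Steatosis and Protein Isoform
    Profiles from Hyperspectral SRS Imaging and cIEF Immunoassays
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for label-free quantitative assessment of non-alcoholic
    fatty liver disease. Segments hyperspectral stimulated Raman scattering
    (SRS) image stacks of liver tissue into lipid, protein and DNA classes
    by spectral phasor analysis, computes percentage steatosis and lipid
    droplet morphometry, and quantifies post-translational-modification
    isoform profiles from capillary isoelectric focusing (cIEF)
    electropherograms. Includes a ground-truthed synthetic-data module
    that emulates normal (microvesicular) and NASH (macrovesicular) liver
    tissue stacks and multi-isoform electropherograms, cohort-level
    differential tables and heat maps, and a combined imaging + proteomics
    report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    tiff,
    jsonlite,
    igraph,
    zoo,
    pracma,
    minpack.lm,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
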
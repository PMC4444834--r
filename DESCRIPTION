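Package: AdaptiveScreen
Title: Adaptive Feedback Microscopy Screening Engine
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Vendor-neutral engine for intelligent (adaptive feedback)
        microscopy screening. A low-resolution search mosaic covering the
        whole sample is captured (or simulated by a built-in virtual
        microscope), objects of interest are located by image analysis
        (tissue-piece detection for tissue microarrays, multi-marker
        rare-event classification for circulating tumour cells, external
        macros, or manual selection), and an optimized high-resolution
        second-scan acquisition plan is generated: single fields for small
        objects and overlap-aware tile grids for large ones, with
        non-informative tiles pruned (NoIR), pixel-to-stage coordinate
        mapping, and objective paracentricity correction. Acquisition
        settings, scan jobs, coordinate lists and experiment templates are
        serialized to a versioned JSON/CSV dialect with byte-exact
        canonical output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports: methods, stats, utils, jsonlite, tiff, EBImage
Suggests: testthat (>= 3.0.0), optparse, igraph, withr
Config/testthat/edition: 3
biocViews: Software, CellBasedAssays, Visualization
RoxygenNote: 7.3.3
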
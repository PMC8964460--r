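Package: memdsn
Title: Membrane Protein Type Prediction from Evolutionary Profiles with
    Dynamically Scalable Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies membrane proteins into the eight canonical types
    (single-span 1-4, multi-span, lipid-anchor, GPI-anchor, peripheral)
    from PSI-BLAST position-specific scoring matrices (PSSMs). Five
    fixed-length evolutionary-profile descriptors (Pse-PSSM, average
    blocks, a four-level discrete wavelet transform, the 2-D discrete
    cosine transform, and histograms of oriented gradients) are
    concatenated into a 1730-dimensional feature vector and classified by
    a lifelong-learning one-vs-rest neural network that freezes
    previously learned parameters and dynamically adds capacity when a
    new class underfits. Includes a PSI-BLAST ASCII PSSM reader/writer, a
    synthetic PSSM generator for end-to-end testing, one-vs-rest
    evaluation metrics (sensitivity, specificity, accuracy, Matthews
    correlation coefficient), and a small command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
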
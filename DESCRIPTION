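Package: snvfold
Title: Differential RNA Secondary Structure Analysis of Point Mutations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Quantifies and visualizes how single- and multiple-nucleotide
    substitutions reshape an RNA's Boltzmann structure ensemble. Computes
    base-pair probability matrices and positional unpaired probabilities
    (accessibilities) for a wildtype sequence and a mutated variant by
    partition-function (inside/outside) folding, globally or over local
    folding windows; derives differential representations (combined
    wildtype/mutant triangle matrices, weakened and strengthened base-pair
    maps, accessibility deltas); scores structural aberration with an
    ensemble relative entropy over the common structure space and a
    region-wise Euclidean-distance/correlation scan with empirical p-values
    from an exhaustive point-mutation background; and renders heatmaps,
    circular plots, arc diagrams and accessibility tracks as deterministic
    SVG and high-resolution PNG. Includes ViennaRNA-dialect PostScript
    dot-plot interoperability and a command-line front end producing a
    reproducible results bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    grDevices,
    graphics,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
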
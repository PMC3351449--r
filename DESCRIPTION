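Package: axonquant
Title: Quantification of Aberrant Dorsal Axon Outgrowth from Confocal Stacks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to quantify aberrant dorsally projecting axons of labeled
    forebrain neurons from multi-channel 3D fluorescence image stacks.
    Implements maximum-intensity z-projection, soma masking, adaptive
    local-mean thresholding and pixel-intensity-sum scoring; converts scores
    to ordinal phenotypic grades (Grade 0-3) and computes group statistics
    (average phenotypic scores, exact tie-aware Mann-Whitney U tests, one-way
    ANOVA with Tukey post hoc, penetrance and dose-response summaries);
    classifies axon emergence sites on single labeled neurons along the
    dorsoventral axis. Includes a ground-truthed synthetic confocal stack
    generator (spheres and swept tubes, Gaussian PSF, Poisson and Gaussian
    camera noise) so every stage of the pipeline can be validated without
    original imaging data.
License: MIT
Encoding: UTF-8
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    digest,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
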
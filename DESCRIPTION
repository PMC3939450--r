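Package: svpuncta
Title: Detection and Quantification of Presynaptic Vesicle Clusters in
    Neuron Co-Culture Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated detection and quantification of cue-induced
    presynaptic (synaptic-vesicle) clusters in fluorescence images of
    neuron/heterologous-cell co-culture assays, and of endogenous synapses
    in mature neuron cultures. Segments neuron, partner-cell and
    vesicle-marker channels by global thresholding, cleans the binary
    masks with morphological openings (small-object removal, cell-body
    elimination, partner-mask dilation), intersects neurite and
    partner-cell masks into size-gated labeled contact regions, and
    reports per-region and per-field synaptic-vesicle cluster frequency,
    density, size and intensity. Includes a ground-truthed synthetic field
    generator for validation and a batch-processing interface with
    fixed-threshold configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    igraph,
    tiff,
    png,
    yaml,
    jsonlite,
    tibble,
    dplyr,
    purrr,
    readr,
    rlang,
    generics,
    ggplot2,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
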
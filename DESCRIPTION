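Package: spikequant
Title: Absolute Microbiota Quantitation with Synthetic Spike-In Standards
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for absolute quantitation of amplicon families (prokaryotic
    16S rRNA, eukaryotic 18S rRNA, fungal ITS) using chimeric synthetic DNA
    spike-in standards. Designs spike constructs with primer-binding sites
    flanking a GC- and length-matched random stuffer, converts picogram doses
    to molecule copies, plans spike levels with an expected read-fraction
    model, demultiplexes and classifies spiked amplicon reads into synthetic
    and microbial counts, applies sample-level quality filters, estimates
    gene copies per gram (or ml) from spike/microbial read ratios, and
    compares relative versus absolute community profiles between sample
    groups. A bundled simulator of spiked sequencing experiments provides
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    MASS,
    stats,
    utils,
    vegan,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
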
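Package: viroclean
Title: Negative-Control-Based Virome Contamination Assessment and Decontamination
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for assessing and removing reagent and cross-study
    contamination in low-biomass virome sequencing studies using negative
    controls (NCs). Builds species-level vOTU abundance tables (95% ANI over
    85% alignment fraction dereplication, breadth-of-coverage filtering,
    RPKM transformation, quality filters), reconstructs per-sample virus
    strains from pileups and compares them with population-level ANI
    (popANI), flags strain identity between samples and NCs at the
    99.999% popANI threshold, performs strain- or species-level
    decontamination of the abundance table, estimates contamination against
    an external negativeome catalog, and ships a multi-study synthetic-data
    generator with ground-truth labels for benchmarking every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    ape,
    vegan,
    jsonlite,
    yaml,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
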
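Package: cyclicproc
Title: Image Processing and Single-Cell Analytics for Cyclic Immunofluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processing and quality-control toolkit for cyclic
    immunofluorescence (CyCIF) and related multi-round multiplex imaging.
    Registers multi-round image stacks on the DAPI channel, subtracts tissue
    autofluorescence using exposure-scaled blank acquisitions (single-baseline
    or round-interpolated), segments nuclei and cells by seeded watershed with
    label expansion, extracts per-cell per-compartment mean intensities, and
    computes staining quality metrics (signal-to-background ratio with a
    bleed-through exclusion gap, quantile dynamic range, Li-threshold tissue
    retention). Includes single-cell normalization (intensity transforms and
    scalers, exclusive-marker-pair background thresholding with 0.02-1
    rescaling, reverse-compartment thresholds, empirical-Bayes batch
    adjustment with control-tissue training modes, mean-only batch
    regression) and batch-effect evaluation (kBET rejection rate, stratified
    sampling, graph clustering, replicate cluster-composition correlation).
    A synthetic-experiment generator produces multi-round images and cell
    tables with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    igraph,
    jsonlite,
    yaml,
    car,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    sva,
    withr,
    optparse
Config/testthat/edition: 3
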
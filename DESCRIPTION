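Package: conjscreen
Title: Analysis of High-Throughput Solid-Plate Conjugation Screens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying bacterial conjugation efficiency from
    arrayed solid-plate mating screens. Converts time-lapse colony image
    stacks (or pre-extracted intensity tables) into calibrated population
    growth curves, segments each curve into an initial flat phase and a
    linear (exponential) phase on the log2 scale to extract lag times and
    growth rates, normalizes experimental matings against interleaved
    control matings pinned at every fourth plate position, and calls
    conjugation-deficient deletion strains with one-sample Wilcoxon tests
    and Benjamini-Hochberg false-discovery-rate correction. Also includes
    a truth-tagged synthetic screen simulator for end-to-end validation,
    gene-set enrichment by Fisher's exact test, and calculators for
    liquid-mating conjugation frequencies and phage efficiency of plating
    from serial-dilution spot counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
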
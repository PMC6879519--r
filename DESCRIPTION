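Package: exrnaperf
Title: Performance Assessment of Biofluid and Extracellular-Vesicle Total RNA Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Statistics layer for quality and performance assessment of total
    RNA sequencing of biofluids and extracellular vesicles. Implements
    spike-in (ERCC/Sequin) titration trueness analysis (expected versus
    observed log2 fold changes, regression slope and adjusted R-squared,
    cumulative deviation fractions), relative RNA concentration estimation
    from endogenous-to-spike read ratios corrected for spike dilution and
    input volume, replicate precision via the area left of the cumulative
    absolute log2-ratio curve (ALC), a single-positive/double-positive count
    cutoff procedure, depth subsampling without replacement, read and gene
    composition summaries, gene-body percentile coverage, gene-detection
    overlap (Jaccard), and a negative-binomial synthetic count generator so
    the whole pipeline is testable without deposited sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
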
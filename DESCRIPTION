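Package: TraceN15
Title: Leaf-Disc 15N Isotope Tracing and qPCR Expression Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantitative analysis toolkit for leaf-disc nitrogen-15
    tracer experiments in Brassica napus and similar systems. Converts
    raw isotopologue intensity tables into fractional and net 15N
    labelling with correction of the AccQTag derivatization M+1
    artifact, combines labelling with internal-standard/external
    calibration quantification into net 15N allocation (nmol 15N per g
    dry weight), computes efficiency-corrected qPCR relative expression
    normalized to the geometric mean of reference genes with GeNorm
    stability ranking and fold-change ratios, provides the group
    comparison statistics used in such studies (one-way ANOVA with
    Tukey HSD compact letters, equal-variance t-tests), calculates PEG
    6000 osmotic potential doses, and ships a synthetic-data generator
    emulating the statistical structure of the real experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
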
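Package: ohpcb
Title: Identification and Quantification of Hydroxylated PCB Metabolites
    from GC-MS/MS Screening Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Suspect screening of hydroxylated polychlorinated biphenyl
    (OH-PCB) metabolites analysed as methylated derivatives (MeO-PCBs) by
    gas chromatography tandem mass spectrometry. Enumerates PCB congeners
    and their hydroxylated derivatives with Ballschmiter-Zell numbering,
    computes molecular and substitution-pattern descriptors, trains
    multiple linear regression and random forest models for relative
    retention times and five-transition MS/MS response factors, ranks
    candidate isomer structures for unknown peaks by weighted retention
    and spectral-similarity ranks, and quantifies identified metabolites
    with predicted relative response factors. Includes a synthetic-data
    generator emulating the statistical structure of MeO-PCB standard
    sets for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    randomForest,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
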
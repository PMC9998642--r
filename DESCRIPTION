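Package: munixd50
Title: MUNIX-Based Progression Biomarkers in the D50 Model of ALS
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits the sigmoidal D50 disease-progression model to longitudinal
    ALSFRS-R scores of amyotrophic lateral sclerosis (ALS) patients and derives
    the electrophysiological progression biomarkers M50, MUSIX200 and CMAP50
    from three-muscle motor unit number index (MUNIX) panels by linear
    time-to-threshold estimation against a healthy-control baseline. Provides
    cohort-level stratified statistics (disease-aggressiveness subgroups, rD50
    phases, median-split Kaplan-Meier survival, separation groups), a seeded
    synthetic-cohort generator emulating the assumed data structure, and a
    reproducible end-to-end pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    minpack.lm,
    survival,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
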
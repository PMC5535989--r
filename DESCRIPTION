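Package: rhythmiR
Title: Rhythmicity Detection in Short Serum-Shock Expression Time Courses
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects rhythmically expressed features (miRNAs, clock genes) in
    short, evenly sampled expression time courses from serum-shock entrained
    cell cultures. Provides bounded cosine (cosinor) fitting with multi-start
    angular-frequency search, threshold-based rhythmicity classification,
    five matrix-randomization null schemes with distribution comparisons,
    Ward clustering of peak phases on the unit circle, hypergeometric
    overlap statistics across cell lines, delta-delta-Ct relative
    quantification of qPCR validation series with a permutation rhythm test,
    and a seeded synthetic-data generator that emulates the assumed
    microarray and qPCR data structure so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3.0)
Imports:
    limma,
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: TimeCourse, Microarray, Normalization, Clustering, qPCR
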
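Package: crossclock
Title: Cross-Platform Comparison of Circadian Transcriptome Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compares bulk transcriptome time series between developmental
    stages profiled on different microarray platforms. Implements
    overall-average scaling of probe-set daily averages, fold-ratio ranking
    with an empirically derived enrichment threshold and replicate
    intersection of enrichment calls; a rank-based 24-hour rhythmicity scan
    (cosine reference waveforms, Kendall S statistic, exact conditional null
    distribution, Benjamini-Hochberg adjustment); conversion of best-fit lags
    to circadian peak phases; and linear plus circular-circular phase
    correlation. A synthetic-data generator with planted enrichment and
    planted rhythms supports end-to-end testing without any download.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
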
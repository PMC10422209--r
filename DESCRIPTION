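Package: odssmri
Title: Objective Dementia Severity Scoring from Structural MRI Slices by
    Supervised Contrastive Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fits a twin-channel (weight-sharing) residual convolutional
    encoder to 2D brain MRI slices with a supervised contrastive loss,
    maps each slice to a 128-dimensional unit-hypersphere embedding, and
    scores neurological function as one hundred times the mean cosine
    similarity to a panel of five healthy-control baseline images.
    Includes a synthetic atrophy-phantom generator for offline testing, a
    minimal NIfTI-1 reader/writer, and an evaluation battery (correlation
    with ordinal disease stage, pairwise t-tests, threshold-based two- and
    three-class metrics, dispersion statistics, Pareto bins).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
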
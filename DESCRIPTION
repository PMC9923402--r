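Package: spherinv
Title: Quantification of Tumour Spheroid Invasion in Brain-Slice Micrographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Segments a fluorescently labelled tumour spheroid in a
    re-sectioned organotypic brain-slice image, delimits the spheroid core
    with an ellipse, isolates and watershed-splits invasive particles
    outside the core, and computes invasion statistics: invasive-edge area,
    average and maximum particle distance from the ellipse edge, and the
    percentage of the spheroid lying within the slice. Includes exact
    point-to-ellipse boundary distances, a synthetic scene generator with
    pixel-exact ground truth for validation, and a batch runner with
    deterministic tabular output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
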
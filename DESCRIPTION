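Package: tsface
Title: Automated Facial Phenotype Screening for Turner Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Landmark-based pipeline for computer-aided screening of Turner
    syndrome from frontal face photographs. Implements geometric and gray-scale
    preprocessing on a 68-point landmark model, three families of facial
    features (pairwise landmark distances, Gabor filter-bank block energies,
    and five local dysmorphology descriptors including Laplacian-of-Gaussian
    nevus detection), PCA reduction with SVM classification of global features,
    AdaBoost score-level fusion of local features, and an age-matched
    case-control evaluation protocol with train/test resampling. Ships a
    seeded synthetic face generator with ground truth so the full pipeline is
    testable without patient imagery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
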
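Package: pareidorsa
Title: Decoding and Representational Similarity Analysis of Illusory-Face
    Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multivariate pattern analysis toolkit for studying how illusory
    faces (face pareidolia) are represented in the human brain. Implements
    leave-one-exemplar-out cross-decoding of fMRI ROI patterns and
    time-resolved MEG sensor patterns (regularized LDA and linear SVM),
    representational dissimilarity matrices with Kendall tau-a model
    comparison and noise ceilings, classical multidimensional scaling,
    threshold-free cluster enhancement (TFCE) sign-permutation inference,
    image-computable model RDMs (graph-based visual saliency and GIST
    descriptors), behavioral-rating RDMs, and fMRI-MEG representational
    fusion. Includes a synthetic-data generator that emulates the
    three-category (human face / illusory face / matched object) yoked
    stimulus design with a configurable time-varying category geometry, so
    the full pipeline is testable end to end without access to recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    e1071,
    jsonlite,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    png,
    MASS
Config/testthat/edition: 3
RoxygenNote: 7.3.3
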
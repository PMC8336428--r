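Package: facemetric
Title: Interpretable Psychological Face Spaces from Pairwise Similarity Judgments
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Recovers a low-dimensional, interpretable "face space" from human
    pairwise similarity judgments. Likert similarity ratings are screened for
    inattentive raters, converted to normalized dissimilarities and averaged
    per image pair; a positive-semidefinite Mahalanobis metric over a
    computer-vision feature space is then learned by regularized convex
    optimization (none, l1, l2 or trace penalties), and the learned space is
    analyzed for dimensionality, per-axis perceptual contributions and
    demographic (LDA) subspaces. An Active Appearance Model front-end builds
    joint shape+texture PCA codes from landmarked face images and inverts them
    to synthesize faces along perceptual axes; a classical multidimensional
    scaling baseline with shortest-path completion of missing dissimilarities
    is included, together with a synthetic-data generator (planted metrics,
    simulated rater populations, procedural cartoon faces) for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    png,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
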
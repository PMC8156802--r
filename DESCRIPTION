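Package: gaitfuse
Title: Decision-Fusion Gait Recognition from Optical Marker Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Identifies walking subjects from short optical motion-capture
    recordings of ten lower-body markers. Per-frame feature vectors (45
    pairwise marker distances plus 10 x-axis marker velocities) are screened
    for unreliable values with kernel-density tail bounds, classified with a
    kernel extreme learning machine (kernel ridge classifier with one-vs-rest
    plus/minus-one coding), and the per-frame fuzzy decisions are combined
    across frames with a reliability-weighted-sum rule whose weights come from
    the principal eigenvector of the decision consistency matrix. Baseline
    fusion rules (sum, product, majority vote, belief, weighted belief), a
    synthetic gait-trajectory simulator, and an evaluation harness for
    accuracy-versus-frame-ratio experiments are included.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
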
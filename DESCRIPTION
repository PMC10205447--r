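Package: actipop
Title: Synthetic Populations with Daily Activity-Travel Schedules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Generates a synthetic population of agents with households and
    full daily activity-travel schedules from aggregate zone statistics,
    municipal cross-tabulations, travel-survey microdata, origin-destination
    matrices, and a building register. The pipeline combines iterative
    proportional fitting (IPF) of joint attribute distributions,
    rank-matching household formation, a generative choice model
    (classifier + biproportional adjustment + probabilistic sampling) for
    advanced attributes, donor-based activity sequence matching, and
    gravity-model destination choice with building-level placement.
    Includes a self-consistent toy-region generator so every stage is
    testable end to end, plus evaluation metrics (marginal percentage
    differences, Jensen-Shannon distance, trip-distance distributions).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nnet,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
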
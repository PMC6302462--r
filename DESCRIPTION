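Package: mwct
Title: Genetic-Algorithm Minimization of the Wilson Central Terminal
Version: 0.1.0
Authors@R:
    person("WCT", "Maintainers", email = "maintainers@example.org", role = c("aut", "cre"))
Description: Tools to minimize the amplitude of the Wilson Central Terminal
    (WCT), the averaged limb-electrode reference used for precordial
    electrocardiogram leads. Given raw limb-electrode potentials from the left
    arm, right arm and left leg, a constrained genetic algorithm searches the
    open probability simplex for the weight tern (alpha, beta, gamma) whose
    weighted mean -- the minimized WCT (M-WCT) -- has minimal amplitude.
    Includes beat-averaged amplitude metrics reported as a percentage of
    Einthoven lead II with QRS-polarity classification, a synthetic
    limb-potential generator based on an equivalent cardiac dipole with a
    planted ground-truth tern, a brute-force grid-search oracle, and a
    command-line interface with CSV/JSON/YAML interchange formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
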
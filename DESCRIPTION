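Package: rmdose
Title: Repeated-Measures Dose-Finding Designs for Phase I Oncology Trials
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for phase I dose-finding designs built on a
    quasi-continuous toxicity endpoint, the normalized total toxicity
    profile (nTTP), observed repeatedly over treatment cycles.  Implements
    the nTTP score from elicited severity weights, a Bayesian linear mixed
    model for longitudinal toxicity fitted by a conjugate Gibbs sampler,
    Bayesian-risk dose recommendation with a 3+3 start-up, a three-stage
    toxicity-efficacy design with adaptive randomization towards higher
    predicted efficacy, proportional-odds scenario generators, and trial
    simulators that report operating characteristics (dose allocation and
    recommendation percentages).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
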
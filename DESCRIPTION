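Package: licktime
Title: Interval-Timing Analysis of Licking Behavior Under Fixed-Time
    Reinforcement and Optogenetic Perturbation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analyzing rodent licking behavior in fixed-time
    reinforcement tasks with optogenetic perturbation of the striatal
    direct and indirect pathways. Provides the canonical event data
    model with an 8-ms inter-lick-interval filter, trial-aligned lick
    rate estimation and power-spectral-density band analysis,
    single-trial peak detection via change-point segmentation and
    Gaussian fitting, bout-onset and stimulation-effect metrics,
    rebound-trial classification, a synthetic lick-raster generator
    emulating the task and stimulation effects, and a leaky
    integrator central-pattern-generator simulator of basal-ganglia
    gating of rhythmic licking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
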
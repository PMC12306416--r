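Package: mfspace
Title: Morphofunctional-Space Analysis of Mammalian Forelimb Lever Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for ecomorphological analysis of mammalian forelimbs:
    osteological measurement handling, percentage functional indices (HRI, EI,
    OI, BIR, BIU, RRI, URI), three static mechanical-advantage lever models of
    the elbow and wrist, allometric size correction by log-log regression
    residuals, principal-component morphospaces with locomotor-habit convex
    hulls, habit-level inference (one-way ANOVA, Tukey-Kramer HSD with compact
    letter displays, one-sample and Welch t-tests for fossils), a triangular
    radial morphofunctional space of the three lever models, and a seeded
    generator of synthetic specimen cohorts for testing the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    multcomp,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
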
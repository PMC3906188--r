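Package: redoxplane
Title: Phenotypic Phase Planes and NAD(H) Shadow-Price Analysis for
    Constraint-Based Yeast Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Flux balance analysis with linear-programming duality for
    genome-scale and toy stoichiometric models, centred on the composite
    reducing-capacity shadow price (the difference between the NADH and NAD
    shadow prices) as an index of how growth responds to the net supply of
    reducing equivalents. Provides phenotypic phase plane scans over glucose
    and oxygen uptake with line-of-optimality detection and availability
    pattern maps, ethanol-biomass production envelopes with growth-coupling
    verdicts, flux variability analysis with span binning and span-vs-oxygen
    profiles, reaction-deletion screens (a priori respiratory presets,
    exhaustive pattern replication, a bounded local search for growth-coupled
    designs, and an NADH-sink modified-model procedure), and two calibrated
    synthetic toy yeast models contrasting Crabtree-positive overflow
    metabolism with Crabtree-negative redox recycling. Reads SBML (Level 3
    flux-constraints extension, with a legacy Level 2 fallback) and
    BiGG-style JSON models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    graphics,
    grDevices,
    tools,
    utils,
    xml2
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
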
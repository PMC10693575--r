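Package: holosim
Title: Agent-Based Simulation of Host Populations and Their Neutrally
    Assembled Microbiomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Forward-in-time Wright-Fisher simulation of a host population
    whose fitness is determined entirely by the composition of its microbiome.
    Microbiomes are assembled neutrally from pre-generated abundance templates
    (scaled Poisson establishment events with logistic within-host growth up to
    a global carrying capacity) and transmitted vertically from the parent
    and/or horizontally from the previous generation's population-wide
    microbial pool. Per-taxon fitness contributions are drawn once per
    simulation from step or truncated-exponential distributions. The package
    tracks ancestral coalescence, fitness-score distributions and pairwise
    Jaccard beta-diversity, and provides scenario presets, replicate
    orchestration and tabular summaries for comparing selection regimes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
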
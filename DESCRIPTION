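Package: gutassembly
Title: Bottom-Up Assembly Analysis of Simple Host Gut Microbiotas
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Statistical pipeline for bottom-up colonization experiments in
    which defined bacterial communities are fed to a gnotobiotic host and
    quantified by colony counts (CFU). Provides replicate-level composition
    summaries, pairwise outcome classification (coexistence versus competitive
    exclusion), bootstrap relative yields, a monoculture-based non-interacting
    null model with Welch tests and FDR control, competitive-hierarchy scoring
    with a permutation null and intransitivity (rock-paper-scissors) scans,
    prediction of three- and multi-species compositions from monocultures or
    pairwise outcomes with assembly rules and simplex/L1 error metrics,
    cross-environment and cross-host-strain comparisons, phylogeny-trait
    Mantel tests, and a synthetic colonization-study generator with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils
Suggests:
    igraph,
    jsonlite,
    testthat (>= 3.0.0),
    vegan
Config/testthat/edition: 3
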
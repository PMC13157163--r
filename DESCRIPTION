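Package: fishnav
Title: Fish-Inspired Spiking Neural Network Navigation with Boundary
    Vector Cells and Hydrostatic Pressure Cues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Simulator for goal-directed underwater navigation driven by
    boundary vector cells (BVCs) and hydrostatic pressure (HP) cues, as
    observed in the goldfish telencephalon. Provides seeded virtual coral
    arenas, electrophysiologically informed neural tuning distributions, a
    minimal Neural Engineering Framework population-coding substrate
    (spiking or deterministic rate mode), five navigation strategy
    variants (null, azimuth, HP, HP-max, HP-default), an A* planner
    baseline in global-map and local-sensing modes, and a full scoring and
    statistical evaluation suite (normalized time/distance, collision
    rate, total score, dynamic time warping trajectory similarity,
    bootstrap errors, effect sizes, Holm-Bonferroni correction).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    igraph,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
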
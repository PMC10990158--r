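Package: dibs
Title: Distributed Information Bottleneck for Information Decomposition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decomposes the information that a set of measured variables carries
    about a relevance variable using the distributed information bottleneck: each
    partial measurement is lossily compressed by its own stochastic channel into a
    Gaussian latent code, and a predictive model is trained on the concatenated
    codes under a beta-annealed trade-off between compression cost and predictive
    information. Includes an exact information oracle for Boolean circuits
    (truth-table entropies, subset mutual informations and the subset frontier),
    precise per-channel mutual-information bounds, information-plane trajectories,
    per-feature allocation heatmaps, distinguishability matrices with threshold
    detection, a synthetic two-type particle-neighborhood generator with radial
    density features emulating structure-rearrangement analyses in amorphous
    solids, and a permutation-invariant per-particle measurement basis with
    positional information maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
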
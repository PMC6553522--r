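Package: pettex
Title: PET Tumor Texture Heterogeneity Analysis on Synthetic Phantoms
Version: 0.1.0
Authors@R: person("pettex", "developers", role = c("aut", "cre"),
    email = "pettex@example.org")
Description: A reproducible pipeline for quantifying intratumoral heterogeneity
    in small-animal FDG-PET images. Generates seeded 3D tumor phantoms with
    controllable zone-size texture, delineates tumors with a deterministic
    three-class fuzzy Bayesian segmentation with a locally adaptive spatial
    prior, quantizes the volume of interest to 64 gray levels, builds the four
    canonical 3D texture matrices (GLCM, GLRLM, GLSZM, NGTDM), computes a
    114-feature radiomic vector (geometric, fractal, first-, second- and
    higher-order), and compares two treatment arms with normality-gated
    Welch/rank tests, greedy correlation-based feature elimination and a
    Bonferroni gate with fold-change reporting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
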
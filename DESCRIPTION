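Package: rewardnet
Title: Reward-Modulated Attractor Network Simulation and Energy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Simulates a recurrent firing-rate network with Hopfield-style
    embedded memories, reward-modulated Hebbian feedforward plasticity
    (Rescorla-Wagner rule), anti-Hebbian recurrent plasticity (Goodall rule),
    and Glauber spike sampling.  Provides generators for binary stimulus
    templates (exposure, chronic, cessation) convolved with Gaussian
    ("resilient") or log-Gaussian ("susceptible") reward-salience kernels,
    Boltzmann energy and exact partition-function analysis for small
    networks, spike-raster cosine similarity with a row-shuffle permutation
    null, and a seeded end-to-end experiment driver.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
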
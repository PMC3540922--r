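Package: pupsyl
Title: Automated Classification of Mouse Pup Isolation-Call Syllables
Version: 1.0.0
Authors@R:
    person("Pupsyl", "Developers", email = "pupsyl@example.org",
           role = c("aut", "cre"))
Description: Detects mouse pup ultrasonic isolation syllables in WAV
    recordings, extracts nine-point dominant-frequency contours from
    spectrograms, discovers syllable categories de novo with a two-step
    cluster analysis (CF-entry pre-clustering, log-likelihood distance,
    agglomerative merging, BIC-based selection of the number of clusters,
    silhouette of cohesion), and classifies syllables into four derived
    types (low, high, one-frequency-step, multi-frequency-step) with
    strain-adjustable frequency boundaries. Includes a synthetic-repertoire
    generator with known ground truth, bimodality-coefficient machinery for
    threshold derivation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils
Suggests:
    cluster,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
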
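Package: tipeplane
Title: Tsallis Improved-Permutation-Entropy Complexity-Entropy Causality Plane
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Feature extraction for complex (especially physiological) time
    series via the Tsallis-entropy complexity-entropy causality plane built on
    an amplitude-aware symbolization. A series is mapped through the Gaussian
    cumulative distribution function, delay-embedded, and quantized so that
    each symbolic pattern retains both the absolute amplitude bin of its first
    element and the amplitude differences to the remaining elements. Sweeping
    the Tsallis weighting parameter q yields a curve of normalized q-entropy
    against statistical complexity (a q-deformed Jensen-Shannon disequilibrium
    times entropy); the locations of the entropy minimum and complexity
    maximum serve as scalar features, optionally per coarse-graining scale.
    Includes seeded generators for white and 1/f noise, autoregressive
    processes, and the Lorenz system, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
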
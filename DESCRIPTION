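Package: neurocurve
Title: Discrete Curvature Morphometry of Traced Neuron Skeletons
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Morphometry of three-dimensional traced neuron skeletons:
    reading and writing skeleton models in a fixed-column PDB-dialect
    coordinate format and in SWC, discrete (Menger) curvature and radius
    estimation along resampled neurite polylines, per-case and per-group
    distribution statistics (Welch comparisons, Shapiro-Wilk checks,
    Pearson/OLS regressions, relative-frequency histograms), and a
    worm-like-chain synthetic cohort generator with known ground truth for
    end-to-end validation of the analysis pipeline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
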
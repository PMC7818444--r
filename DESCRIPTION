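Package: srcflow
Title: Stimulus-Response Correlation Analysis for Continuous EEG Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures the strength of continuous visually evoked responses as
    the temporal correlation between a time-varying stimulus feature (such as
    optic-flow magnitude of a video) and multichannel EEG. Implements the full
    workflow: Horn-Schunck optic flow and temporal-contrast feature extraction,
    EEG preprocessing (resampling, high-pass filtering, robust PCA artifact
    suppression, ocular regression, iterative channel and sample rejection),
    canonical correlation analysis with temporal embedding of the stimulus,
    condition-wise spatial and temporal response functions, alpha-band power
    maps, and nonparametric statistics (Wilcoxon tests, subject-permutation
    tests with false-discovery-rate control). Includes a synthetic-data
    generator with known ground truth so the entire pipeline can be validated
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
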
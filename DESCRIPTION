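Package: gradcptr
Title: Analysis of Gradual-Onset Continuous Performance Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for gradual-onset continuous performance task (gradCPT)
    behavioral data: stimulus-schedule generation, keypress-to-trial response
    assignment and outcome classification, signal-detection sensitivity (d')
    and reaction-time summaries, variance time courses (VTCs) with Gaussian
    smoothing and fluctuation-frequency estimation, amplitude-modulated
    hemodynamic-response regressors for fMRI design matrices, and default
    Bayes factors with credible intervals for Pearson correlations and paired
    t contrasts. Includes a latent fluctuating-attention observer simulator
    so the full pipeline can be exercised on synthetic sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
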
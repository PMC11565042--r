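Package: trialqc
Title: Trial-Level Data-Quality Metrics for EEG/ERP Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Computes data-quality metrics for trial-level EEG/ERP single
    scores (time-window mean amplitudes or per-epoch spectral power):
    split-half internal-consistency reliability with Spearman-Brown
    correction, within-subject Cohen's d against a baseline constant or
    between conditions, and the standardized measurement error (analytic
    and bootstrapped), each overall and as a function of increasing trial
    counts with percentile confidence intervals from the resampling
    distribution. Includes a variance-components simulator of trial-level
    scores with closed-form oracle values for every metric, a command-line
    interface, and threshold-annotated reliability-curve plots.
License: MIT + file LICENSE
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
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
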
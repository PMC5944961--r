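Package: octavesad
Title: Species Abundance Distribution Model Selection on Preston Octaves
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Fits and compares species abundance distribution (SAD) models
    on the Preston octave (log2 abundance) scale. Provides octave binning of
    per-species abundance tables in two dialects (half-open classes and
    Preston's boundary-halving rule), least-squares fitting of seven SAD
    models (geometric series, broken stick, overlapping niche, logseries,
    lognormal, logCauchy and log-sech) by Levenberg-Marquardt regression,
    goodness-of-fit assessment (chi-square test, adjusted coefficient of
    determination) and model selection by AIC/BIC, extrapolation of total
    species richness from the area under the untruncated fitted curve, and
    left-truncated unit-area probability curves for comparing community
    layers. A synthetic-community generator draws abundances from each
    model's generative form for fixtures and parameter-recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, tools, minpack.lm, pracma, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'octavesad-package.R'
    'AllGenerics.R'
    'AllClasses.R'
    'utils.R'
    'models.R'
    'binning.R'
    'io.R'
    'fitting.R'
    'gof.R'
    'selection.R'
    'curves.R'
    'simulate.R'
    'recovery.R'
    'workflow.R'
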
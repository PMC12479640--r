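Package: swallowCA
Title: Acoustic and Perceptual Analysis of Swallowing Sounds from
    Cervical Auscultation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing swallowing sounds recorded by cervical
    auscultation during feeding observations, with an emphasis on preterm
    neonates. Extracts per-swallow acoustic profiles (duration, peak
    frequency by a cumulative-spectral-power criterion, peak amplitude and
    clip-corrected peak power in decibels) from annotated PCM WAV
    recordings using a Butterworth high-pass filter, short-time framing
    and Welch periodogram spectral estimates. Encodes a perceptual rating
    schema for pre-, during- and post-swallow sounds with presence and
    consistency rules, two-rater consensus and a rule-based
    coordinated/uncoordinated swallow classifier. Provides inter-rater
    agreement statistics (percent agreement, Cohen's kappa,
    prevalence-adjusted bias-adjusted kappa) with interpretation bands,
    cohort descriptive statistics, correlation inference with Fisher-z
    confidence intervals and a correlation-based sample-size calculation,
    plus a synthetic-data generator so every pipeline stage is testable
    without clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
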
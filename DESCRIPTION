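Package: cortexdyn
Title: Cortical Dynamics Signatures from Resting-State Time Series
Version: 0.1.0
Authors@R: person("Cortexdyn", "Developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to extract six parameters of local cortical population
    dynamics (aperiodic exponent, knee frequency, aperiodic AUC, Hurst
    exponent of alpha-envelope fluctuations, alpha power and alpha peak
    frequency) from parcel-level resting-state time series, to build
    group-difference maps ("psychosis signatures", "drug-effect maps"),
    and to relate such maps with spatial-autocorrelation-preserving
    spin-permutation tests, anatomical-axis polynomial fits, canonical
    correlation analysis, individual pattern-similarity analyses with
    symptom coupling, and permutation-tested group classification.
    Includes a synthetic-cohort generator emulating parcellated cortical
    maps with smooth spatial autocorrelation and spectrally structured
    time series, so the full pipeline is testable without access to
    clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
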
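Package: ecogpred
Title: Predictive Auditory Mechanisms in Intracranial Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for intracranial electrophysiology of
    predictive processing in human auditory cortex. Implements
    frequency-domain bandpass Hilbert filtering with sigmoid flanks,
    inter-trial phase coherence with jittered-bootstrap nulls,
    phase-resolved amplitude encoding, prediction-interval analysis,
    acoustic envelope and edge extraction from audio, rank-2
    non-negative matrix factorization of supratemporal responses into
    sustained and transient classes with archetype transfer to
    articulation epochs, traveling-wave velocity estimation, and
    behavioral detection and stimulation-outcome statistics. Includes a
    synthetic-data generator that plants the relevant response
    archetypes (envelope-locked high gamma, edge-locked theta phase
    reset with post-stimulus persistence, mediolateral traveling-wave
    lags, articulation-suppressed onset transients) so every analysis
    can be validated by parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    signal,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
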
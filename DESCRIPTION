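Package: fringep3
Title: Fringe-P3 Analysis of Familiar-Face Breakthrough in RSVP EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the Fringe-P3 concealed-information paradigm: detection
    of breakthrough into awareness of familiar faces presented in rapid serial
    visual presentation (RSVP) streams, from epoched EEG. Provides a synthetic
    multi-participant EEG generator with the signal structure the paradigm
    assumes (stimulus-locked theta-band burst, late positivity, 1/f and alpha
    background, SSVEP, drift, blinks, latency jitter), the standard
    preprocessing chain (zero-phase band-pass and notch filtering, resampling,
    mastoid re-referencing, epoching, amplitude-based artifact rejection,
    linear detrending of the combined-condition average, baseline correction),
    contrast-orthogonal 100 ms window placement on aggregated ERPs (aERPt) and
    on the aggregated grand average of trials (AGAT), per-participant
    Monte-Carlo randomisation tests on mean-amplitude differences,
    event-related spectral perturbation (ERSP) and inter-trial coherence (ITC)
    with positive-sum permutation inference, group-level paired t tests with
    pooled-condition-SD effect sizes, and signal-detection and rating-scale
    behavioral measures, orchestrated by a seeded end-to-end pipeline.
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
    testthat (>= 3.0.0)
Config/testthat/edition: 3
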
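Package: meglat
Title: Automated Dipole Localization and Language Laterality Mapping for MEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated single equivalent current dipole (ECD) analysis of
    magnetoencephalography (MEG) data for language mapping, together with the
    three distributed inverse methods it is usually compared against: the
    minimum norm estimate (MNE), dynamic statistical parametric mapping (dSPM)
    and the dynamic imaging of coherent sources (DICS) frequency-domain
    beamformer.  Provides a single-sphere (Sarvas) forward model for planar
    gradiometer arrays, a synthetic-data generator for evoked fields,
    oscillatory event-related (de)synchronization epochs and empty-room noise,
    sensor-level preprocessing (zero-phase filtering, epoching, automated
    artifact rejection, multitaper time-frequency analysis), hemispheric
    laterality indices with test-retest reliability metrics, and a
    localization-error benchmark harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    signal,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
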
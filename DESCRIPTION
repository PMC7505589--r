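Package: bercouple
Title: Coupling of Breath-by-Breath Gas Exchange with Cerebral Hemodynamic Fluctuations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how breath-by-breath respiratory gas-exchange
    metrics (the O2-CO2 exchange ratio bER, within-breath excursions of PO2 and
    PCO2, end-tidal pressures, and respiration volume per time) couple with
    low-frequency cerebral hemodynamic fluctuations measured by transcranial
    Doppler velocimetry and BOLD fMRI. Implements breath-phase parsing and
    gas-line delay correction for capnogram/oxigram traces, beat-resolved
    processing of Doppler velocity envelopes, Morlet wavelet transform
    coherence with AR(1) red-noise Monte Carlo significance and a
    quadrant-resolved time-averaged coherence profile, voxelwise regression
    mapping with Monte Carlo cluster-extent correction, seed-based
    connectivity, and cerebrovascular-reactivity mapping under a CO2 block
    paradigm. A synthetic-data module generates coupled physiological and
    imaging records with known ground truth so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    rlang,
    RNifti,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
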
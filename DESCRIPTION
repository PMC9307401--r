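Package: prestim
Title: Prestimulus-Time and Feedback ERP Analysis for Loss-Gain Gambling EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of event-related potentials (ERPs)
    recorded during a loss-gain gambling task. Provides a synthetic-EEG
    generator with known ground truth (1/f background, blink artifacts,
    condition-dependent ERP templates on a 10-20 montage), a preprocessing
    chain (constant-method baseline correction, correlation-gated
    independent-component ocular removal, amplitude-threshold epoch
    rejection, epoch averaging, zero-phase low-pass filtering, common
    average reference), the prestimulus-time (PT) statistic measuring when
    two condition-average waveforms last intersect before a decision, the
    medial-frontal-negativity (MFN) latency and loss/gain delta-amplitude
    statistics, scalp topographic maps, permutation-based group inference,
    EDF+ input/output, and a reproducible pipeline orchestrator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    signal,
    mgcv,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
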
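Package: dyadsync
Title: Interbrain Synchronization Analysis for Dyadic EEG Hyperscanning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of dyadic (two-person) EEG hyperscanning
    recordings: deterministic preprocessing (downsampling, notch, average
    reference, band-pass into canonical delta/theta/alpha/beta bands),
    intersubject correlation via correlated component analysis, interbrain
    functional connectivity with the phase lag index (scalp) and the
    time-averaged phase locking value (cortex), a standardized minimum-norm
    (sLORETA-style) linear inverse with atlas-based ROI reduction,
    network-based cluster-permutation statistics with family-wise error
    control, binary graph-theoretic network metrics, and paired-t power
    utilities. Includes a synthetic-data generator producing dyads with
    known ground-truth interbrain phase coupling so the full pipeline is
    testable without human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    MASS,
    igraph,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'accessors.R'
    'conn.R'
    'edf.R'
    'graph.R'
    'isc.R'
    'nbs.R'
    'pipeline.R'
    'power.R'
    'prep.R'
    'source.R'
    'synthgen.R'
    'utils.R'
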
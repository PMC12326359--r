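Package: pfewave
Title: Kinetic Modeling of Steady-State Catalytic Voltammetry of Hydrogenases
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analyzing protein film electrochemistry of bidirectional
    H+/H2 electrocatalysis. Implements the four-parameter steady-state catalytic
    waveform, the ordered EECC catalytic-cycle rate expressions and their pH and
    H2-concentration laws, stage-1 extraction of catalytic potentials and
    limiting currents from single voltammograms, stage-2 sequential fitting of
    pH and H2 series to recover thermodynamic and kinetic parameters, an
    equilibrium four-state model for FTIR pH titrations of the H-cluster, CV
    file handling with Methods-level preprocessing (sweep averaging, blank
    subtraction, film-loss normalization, reference-electrode conversion), and
    a seeded synthetic-data generator for closed-loop parameter-recovery
    benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
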
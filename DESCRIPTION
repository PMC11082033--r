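Package: rvadflow
Title: Lumped-Parameter Hemodynamics and Thrombosis-Risk Flow Metrics for
    Ventricular-Assist-Device-Supported Circulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Closed-loop lumped-parameter model of a severely failing
    biventricular circulation supported by two rotary blood pumps, with
    time-varying-elastance chambers, diode-type hydraulic valves and a
    head-flow-speed pump law, integrated to periodic steady state and
    summarised into the standard clinical hemodynamic indices. A companion
    set of flow-metric kernels computes thrombosis-risk quantities on
    time series of velocity fields over masked structured grids: blood
    stagnation volume, Carreau effective viscosity, wall shear stress and
    its time average with band classification, Q-criterion, kinetic
    energy, Eulerian washout and blood residence time. A synthetic
    ventricle-flow generator with a controllable cannula-depth surrogate
    ties the two together for end-to-end depth-trend studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    jsonlite,
    Matrix,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
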
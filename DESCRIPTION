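Package: dualtracer
Title: Kinetic Modelling of Sequential Dual-Tracer Dynamic PET
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Compartment-model analysis of dynamic PET time-activity curves,
    with support for sequential same-session dual-tracer studies in which a
    low-dose reversible tracer (1-tissue compartment, volume of distribution
    V_T) is followed in the same scan by a full-dose irreversibly trapped
    tracer (2-tissue irreversible model, net influx rate K_i) of the same
    isotope.  Provides Levenberg-Marquardt and separable-parameter-space
    fitting with blood fraction and delay estimation, Logan and Patlak
    graphical estimators, residual first-tracer signal correction by
    triexponential projection of the input function, simultaneous dual-tracer
    fitting, a synthetic-data generator with count-limited noise, and
    dose/duration subsampling studies for protocol design.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    minpack.lm,
    pracma,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
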
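Package: mesosaxs
Title: Small-Angle Scattering and Formulation Analytics for Lyotropic
    Mesophase Nanoparticles
Version: 0.1.0
Authors@R:
    person("mesosaxs", "maintainers", email = "mesosaxs@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis pipeline for hexosome and cubosome drug
    nanocarriers. Implements a composite small-angle X-ray scattering model
    (piecewise Guinier-Porod terms for the overall particle and its internal
    cylinder structures, Lorentzian lattice peaks, flat background) with
    continuity-constrained fitting and derived structural metrics; lyotropic
    mesophase peak indexing (hexagonal HII, cubic Pn3m/Im3m/Ia3d, lamellar)
    with lattice constants and temperature-series transition detection;
    formulation assays (critical aggregation concentration breakpoint fits,
    calibration-based drug quantification, encapsulation efficiency,
    cumulative in-vitro release with dialysis sampling correction); FFT-based
    lattice-spacing estimation from micrograph-like images; and seeded
    synthetic-data generators for all of the above, including presets for
    published unloaded and drug-loaded systems.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
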
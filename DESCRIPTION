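Package: nsad
Title: Neutron Single-Wavelength Anomalous Diffraction at Desk Scale
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Feasibility physics and a simulated end-to-end phasing pipeline
    for neutron single-wavelength anomalous diffraction (SAD) on a
    perdeuterated protein crystal carrying one strongly absorbing isotope
    (113Cd). Provides Breit-Wigner resonance scattering lengths and
    absorption cross sections, linear attenuation coefficients, an
    anomalous-signal estimator, a synthetic P212121 crystal and Friedel-pair
    intensity simulator, merging statistics with anomalous pairs kept
    separate, anomalous-difference Patterson synthesis with Harker-section
    site solving, and SAD phase estimation with hand selection and no
    density modification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown,
    jsonlite
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
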
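Package: radbiosphere
Title: Landscape-Scale Compartment Modelling of Radionuclide Transport and Dose
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A time-varying linear compartment simulator for the long-term
    transport and accumulation of radionuclides in interconnected biosphere
    objects undergoing sea-to-lake-to-wetland succession, with optional
    conversion to agricultural land. Radionuclide retention and biological
    uptake are modelled with equilibrium distribution coefficients (Kd) and
    concentration ratios (CR), decay chains are solved jointly with
    transport, and annual doses to a representative individual of the most
    exposed group are summarised as Landscape Dose conversion Factors (LDF)
    for constant and pulse releases. Includes Monte Carlo uncertainty
    propagation with Spearman rank sensitivity analysis, a synthetic
    landscape generator, JSON configuration input/output and a command-line
    interface.
License: MIT
Encoding: UTF-8
Imports:
    Matrix,
    jsonlite,
    lhs,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
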
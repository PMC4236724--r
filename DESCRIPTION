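Package: igfnet
Title: Mass-Action Modelling of the IGF1-IGFBP-IGF1R Binding Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the extracellular insulin-like growth factor 1 (IGF1)
    binding network in cultured cells with mass-action kinetics: reversible
    binding of IGF1 to a lumped IGF-binding-protein (IGFBP) pool and to the
    type 1 IGF receptor (IGF1R), plus first-order cell-mediated ligand
    depletion. Provides stiff ODE integration to a quasi-steady-state
    receptor-occupancy readout, an independent closed-form binding
    equilibrium solver, calibration of the depletion rate and total IGFBP
    levels from conditioned-media measurements, a linear map from per-cell
    receptor occupancy to proliferation with a receptor-saturation cap,
    in-silico comparison of IGF1-neutralizing versus IGF1R-blocking
    antibodies over a configurable test matrix, and seeded synthetic-data
    generators for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    jsonlite,
    yaml,
    readr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
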
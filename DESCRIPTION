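Package: lvdilute
Title: Lotka-Volterra Competition Under Serial Dilution and Fluctuating
    Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Analysis of two- and three-species microbial competition under
    growth-dilution (serial transfer) cycles.  Implements the Lotka-Volterra
    competition model with an added community-wide mortality rate, its
    reparametrization into effective competition coefficients, closed-form
    equilibria and stability, outcome classification (exclusion, coexistence,
    bistability), the logarithmic dilution-factor/mortality mapping with
    geometric-mean time-averaging of fluctuating schedules, a serial-transfer
    simulator with bifurcation diagrams and separatrix location,
    time-to-threshold growth-rate estimation from optical-density curves,
    competition-coefficient estimation from outcome-boundary dilution factors,
    beta-posterior fraction statistics for colony counts, and a synthetic-data
    generator emulating plate-based coculture experiments with known ground
    truth.
License: MIT
Encoding: UTF-8
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
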
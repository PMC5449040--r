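Package: hpcoil
Title: Random-Coil Pressure Coefficients for High-Pressure NMR Chemical Shifts
Version: 0.1.0
Authors@R:
    person("hpcoil", "maintainers", email = "hpcoil@example.org", role = c("aut", "cre"))
Description: Reference library of backbone amide 1H and 15N pressure
    coefficients (delta0, B1, B2) of the 20 canonical amino acids measured in
    random-coil model tetrapeptides, together with the quadratic
    pressure-shift model, a multistate Boltzmann ensemble model with
    pressure-dependent free energies (partial molar volume and
    compressibility factor), least-squares fitting of pressure series, a
    correction pipeline that subtracts random-coil pressure responses from
    protein peak tracks, a synthetic-data generator emulating 0.1-200 MPa
    titrations, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
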
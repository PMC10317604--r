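Package: capilsep
Title: Capillary-Driven Blood Plasma Separation in Surface-Patterned Microchips
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reduced-order modelling of passive blood-plasma separation in a
    surface-patterned microfluidic chip. Solves quasi-one-dimensional
    capillary- and gravity-driven filling of a segment network with a
    hydrophobic burst barrier and coagulation-induced viscosity growth,
    couples it to a finite-volume advection-diffusion solver for plasma mass
    fraction on the moving filled domain with a cell-retention junction, and
    calibrates the free parameters to measured separated-plasma volumes by
    least squares. Includes plasma purity and recovery metrics from cell
    counts, goodness-of-fit statistics, extrapolation to near-complete
    separation, and a synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
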
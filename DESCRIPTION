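Package: peristream
Title: Peristaltic Streaming of a Compressible Maxwell Fluid in a Microchannel
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.net", role = c("aut", "cre"))
Description: Perturbation solution for the flow driven by a traveling wave of
    wall deformation in a two-dimensional flexible-wall microchannel filled
    with a compressible Maxwell fluid (linear or upper-convected variant).
    Computes the first-order (order-epsilon) traveling-wave velocity and
    pressure fields in closed form, the second-order time-averaged streaming
    flow by exact integration of the mean-flow forcing, and the derived
    observables: the mean velocity perturbation function G(y), the mean axial
    velocity, the net flow rate and the wall streaming velocity.  An
    independent Chebyshev collocation solver for the first-order boundary
    value problem provides numerical ground truth, and shipped sweep recipes
    reproduce the parametric studies of the model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    ggplot2
Config/testthat/edition: 3
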
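Package: debatch
Title: Dynamic Energy Budget and Monod Models for Microbial Batch Culture
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates and fits a two-reserve, one-structure Dynamic Energy
    Budget (DEB) model of bacterial growth in batch culture under carbon and
    nitrogen substrate limitation, together with a baseline two-substrate
    Monod model. Growth fluxes from the carbon and nitrogen reserves are
    merged by a synthesizing unit; maintenance is paid from mobilized
    reserves with a switch-model fallback to structure; cultures die when a
    reserve can no longer cover its maintenance. Includes C-mol elemental
    bookkeeping of biomass composition, weighted nonlinear least-squares
    parameter estimation across limitation scenarios by the Nelder-Mead
    simplex, nonsimultaneous prediction intervals, a synthetic-observation
    generator emulating triplicate batch-culture assays, and scripted
    simulation and parameter-recovery experiments.
License: MIT + file LICENSE
Encoding: UTF-8
NeedsCompilation: yes
Depends: R (>= 4.0)
Imports:
    deSolve,
    minpack.lm,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
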
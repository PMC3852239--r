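Package: kineticizer
Title: Thermodynamically Consistent Kinetic Models from Stoichiometric
    Metabolic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Converts a stoichiometric metabolic network plus sparse flux,
    concentration and kinetic-constant data into a fully parameterised
    kinetic model that obeys the laws of thermodynamics and actualises a
    predefined steady state.  The pipeline determines a unique stationary
    flux distribution by geometric flux balance analysis, extracts the
    flux-carrying subnetwork, assigns metabolite concentrations and
    equilibrium constants satisfying the Wegscheider loop conditions,
    balances Michaelis and catalytic constants per reaction under the
    Haldane relationship, inserts common modular (generalised reversible
    Michaelis-Menten) rate laws, and rescales maximal velocities so the
    model reproduces the target steady state.  Downstream analyses cover
    Jacobian stability, metabolic control analysis and perturbation
    simulations; a deterministic toy-fixture generator provides networks
    with known ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    xml2
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
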
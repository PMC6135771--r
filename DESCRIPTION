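Package: hairpinREX
Title: Replica-Exchange Monte Carlo and Folding Thermodynamics of
    GB1p-Series Beta-Hairpins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Coarse-grained replica-exchange Monte Carlo sampling and
    two-state folding analysis for GB1p-series beta-hairpin peptides
    (GB1p, HP5A, GB1m3). Provides a bead-level hairpin model with tunable
    loop flexibility and native-contact strengths, an exactly solvable
    zipper model used as an analytic oracle, a temperature replica-exchange
    engine with exponential ladders and Metropolis exchanges, structural
    observables (native backbone H-bonds, sidechain contacts, helicity,
    loop and end-to-end distances), folding thermodynamics estimators
    (folded/unfolded populations, free energy, energy and entropy of
    folding, melting temperatures, half-split standard errors), and
    free-energy landscape construction (1D/2D -kT ln p surfaces,
    minimal-energy paths, principal-component landscapes with Kabsch
    superposition). Trajectories round-trip through multi-model PDB plus a
    tab-separated energy sidecar.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    parallel,
    stats,
    utils,
    tools,
    graphics,
    grDevices,
    yaml,
    jsonlite,
    bio3d,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
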
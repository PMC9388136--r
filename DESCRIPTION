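Package: mtnetsim
Title: Agent-Based Simulation of Microtubule Networks Organized by Motile Cross-Linkers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Brownian-dynamics simulation of active microtubule networks
    self-organized by symmetric (kinesin-5/KIF11-like) and asymmetric
    (kinesin-14/HSET-like) motile cross-linkers in a thin, laterally periodic
    box. Filaments are polar, bendable, inextensible lines that nucleate from
    fixed seeds and grow from a shared, finite tubulin pool; cross-linker
    complexes are pairs of motor or diffusive units joined by a Hookean spring,
    with force-dependent unbinding, linear force-velocity stepping,
    thermodynamically consistent force-biased lattice hopping, and
    configurable end-dwelling policies. Includes scenario presets for
    KIF11-only, HSET-only and mixed-motor networks at full or reduced scale,
    and a quantification pipeline for signed microtubule sliding speed and
    per-cross-linker-type bundle/aster cluster sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
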
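Package: condcap
Title: Coarse-Grained Capsid Assembly in Implicit Biomolecular Condensates
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and theory toolkit for virus capsid self-assembly
    coupled to liquid-liquid phase separation. Provides patchy rigid-body
    subunit models (pentagonal subunits assembling into dodecahedral shells,
    triangular subunits assembling into T=1 icosahedral shells), rigid-body
    Langevin dynamics in a periodic box with an implicit spherical condensate
    potential, self-consistent ideal-solution and hard-sphere
    (Carnahan-Starling / BMCSL) two-state equilibrium theories of
    condensate-coupled assembly, closed-form kinetic scaling estimates
    (diffusion time, nucleation speedup, median assembly time), and
    bond-graph trajectory analytics (cluster detection, yields, partition
    coefficients, malformed-structure statistics).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
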
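Package: epivertex
Title: Vertex-Based Mechanics of Disordered Epithelial Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates equilibrium cell packings of a planar epithelial
    monolayer using a vertex-based mechanical model with periodic boundary
    conditions. Computes per-cell and tissue-level stress tensors from cell
    geometry, classifies the (line tension, contractility) parameter space,
    derives bulk and shear elastic moduli, and fits model parameters to
    observed mean cell area per polygonal class by grid likelihood. Includes
    Matern type II seeding with periodic Voronoi initial conditions, T1
    (intercalation) and T2 (extrusion) topological transitions, and
    enforcement of an imposed isotropic boundary load.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
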
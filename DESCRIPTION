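Package: branchrd
Title: Turing Reaction-Diffusion Simulation of 3D Branching Morphogenesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a four-field activator-inhibitor-substrate-differentiation
    reaction-diffusion system on a regular 3D grid to model branching
    morphogenesis of lung-like tissues, covering both side-branching and
    tip-splitting growth modes. Provides homogeneous steady-state and linear
    (Turing) stability analysis with dispersion relations, 3D skeleton-based
    branch morphometrics (tissue extraction, skeletonization, branch-point and
    tip detection, bifurcation spatial separations), a five-class branch
    pattern classifier, transverse concentration profiling with peak counting,
    parameter-domain sweeps, and scenario runners for seeded-bud and
    external-gradient fabrication experiments. Snapshots are written as legacy
    ASCII VTK structured points for downstream 3D visualization.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    rlang,
    generics,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
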
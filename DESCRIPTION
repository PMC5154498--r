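Package: memscape
Title: Spatial and Kinetic Analysis of Coarse-Grained Membrane-Receptor Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify how lipid composition and receptor conformation
    shape the lateral organization of G protein-coupled receptors in
    multi-component coarse-grained membrane models. Computes per-lipid tail
    order angles, gridded order/thickness/density fields, sphingomyelin
    enrichment in ordered regions, helix-resolved azimuthal profiles, and
    receptor tilt; membrane modulation profiles between receptor pairs with
    angular interface windows and line-of-centers occlusion; lipid residence
    times, sterol flip-flop detection and rate estimation, and a cholesterol
    kinetic network with committor/flux pathway decomposition; dimer interface
    detection from backbone contact maps, interface naming and clustering,
    oligomer detection, interface RMSD, and Bayesian multinomial interface
    frequency estimation. Includes a synthetic coarse-grained trajectory
    generator with planted ground truth so every analysis stage is testable
    without molecular dynamics input.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d,
    withr
Config/testthat/edition: 3
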
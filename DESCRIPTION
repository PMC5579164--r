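Package: annulipid
Title: Annular Lipid Organization and Dynamics Around Membrane Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Post-processing analyses for coarse-grained simulations of
    membrane proteins in lipid bilayers: per-leaflet two-dimensional lipid
    headgroup density maps, lateral radial distribution functions around the
    transmembrane region, lateral diffusion coefficients resolved in radial
    annuli around the protein with block-averaged errors, per-residue
    protein-lipid contact tables mapped onto structures, and cholesterol
    flip-flop accounting. Includes a Brownian-dynamics generator of
    two-leaflet periodic membrane patches with known ground truth
    (position-dependent diffusivity, radial enrichment wells, stochastic
    leaflet exchange) used to validate every estimator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    ggplot2
Config/testthat/edition: 3
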
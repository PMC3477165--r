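Package: mmcg
Title: Hybrid Molecular-Mechanics/Coarse-Grained Simulation of Membrane
    Receptor-Ligand Complexes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale simulator for the hybrid molecular-mechanics /
    coarse-grained (MM/CG) scheme used to study ligand binding in membrane
    receptors. The binding-site region is treated atomistically, the protein
    frame as a C-alpha Go model with Morse-type native contacts, and the lipid
    bilayer and water droplet are mimicked by five level-set boundary walls
    with capped, shifted forces. Includes stochastic (Langevin) dynamics with
    SHAKE constraints, synthetic test systems (helical bundles, ligands,
    rigid water droplets), and trajectory analysis tools (RMSD, RMSF,
    velocity autocorrelation, radial distribution functions, pair distances).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
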
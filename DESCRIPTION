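Package: amdmem
Title: Accelerated-MD Reweighting and Peptide-Membrane Interaction Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis toolkit for accelerated molecular dynamics (aMD)
    trajectories of membrane-active peptides. Implements the aMD boost
    potential and its dual-boost parameter recipe, canonical-ensemble
    reweighting of boosted trajectories by exponential and truncated
    Maclaurin-series Boltzmann factors, dihedral principal component
    analysis with density-based extraction of the most populated
    conformational clusters, reweighted potentials of mean force over one-
    and two-dimensional reaction coordinates, acyl-chain deuterium order
    parameters, peptide-to-membrane-center distance series, and
    residue-headgroup contact fractions. Ships synthetic-data generators
    with known ground truth (boosted Metropolis samples from toy
    potentials, planted von Mises torsion clusters, oriented bond-vector
    sets, toy membrane systems) so every stage is testable end to end
    without external trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
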